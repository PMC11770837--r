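term	synonyms
notably	markedly|strikingly|clearly
markedly	notably|strikingly|clearly
strikingly	notably|markedly|clearly
clearly	notably|markedly|strikingly
recent	previous|earlier|prior
previous	recent|earlier|prior
earlier	recent|previous|prior
prior	recent|previous|earlier
study	analysis|report|experiment
analysis	study|report|experiment
report	study|analysis|experiment
experiment	study|analysis|report
patients	subjects|participants
subjects	patients|participants
participants	patients|subjects
observed	noted|documented
noted	observed|documented
documented	observed|noted
significantly	substantially|considerably
substantially	significantly|considerably
considerably	significantly|substantially
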