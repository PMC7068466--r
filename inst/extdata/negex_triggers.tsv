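pre	no
pre	not
pre	without
pre	denies
pre	denied
pre	deny
pre	negative for
pre	no evidence of
pre	no sign of
pre	no signs of
pre	no history of
pre	no complaints of
pre	free of
pre	rules out
pre	ruled out
pre	rule out
pre	absence of
pre	never had
pre	resolved
post	unlikely
post	ruled out
post	rule out
post	was ruled out
post	has resolved
post	is unlikely
post	not present
term	but
term	however
term	although
term	though
term	except
term	nevertheless
term	yet
term	apart from
term	aside from
term	secondary
term	cause of
term	causes of
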