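{"command":"train","options":{"seed":1,"out":"run","debug":false,"cutoff":"default","sampling":"normal","split":"8:1:1","variant":"full","help":false},"time":"2026-09-21T07:40:39"}
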