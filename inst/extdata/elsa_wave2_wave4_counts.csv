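state,robust,prefrail,frail,dead,dropped_out
robust,937,519,51,79,640
prefrail,335,546,189,178,659
frail,10,43,84,133,247
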