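## channel layout shared by the simulator and the encoder input encoding

N_SIGNALS <- 12L   # wearable channels
N_QUALITY <- 5L    # channels carrying a 0-100 quality index
QBLOCK <- 101L     # one-hot-style block length per quality channel
ENC_INPUT_DIM <- N_QUALITY * QBLOCK + (N_SIGNALS - N_QUALITY)  # 512
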