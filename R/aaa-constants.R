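# Shared constants (loaded first).

# Soft-tissue HU window and the canonical 128-bin discretization:
# HU = CT_index * 3.125 - 200 maps edge indices 0..128 onto [-200, 200].
HU_RANGE <- c(-200, 200)
N_BINS <- 128L
BIN_WIDTH <- diff(HU_RANGE) / N_BINS  # 3.125 HU

TISSUES <- c("fat", "connective", "muscle")
LABEL_LEVELS <- c(TISSUES, "background")

# Continuous-value tissue thresholds: midpoints of the integer interval
# bounds ([-200,-10] fat, [-9,40] connective, [41,200] muscle).
FAT_CONNECTIVE_SPLIT <- -9.5
CONNECTIVE_MUSCLE_SPLIT <- 40.5

# Validity bounds for component parameters. sigma and alpha bounds keep
# exp/erfc numerically stable; mu is confined to the soft-tissue window.
PARAM_BOUNDS <- list(
  N     = c(0, Inf),
  mu    = c(-200, 200),
  sigma = c(0.1, 200),
  alpha = c(-20, 20)
)
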