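# Package-wide constants (file sorts first in collation order).

# Fixed channel order of every IMU stream: linear acceleration then angular
# velocity, device units.
IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

# The five per-frame annotation codes: -1 unknown, 0 no activity,
# 1 nonfunctional movement, 2 nontask-related functional, 3 task-related.
FAABOS_CODES <- c(-1L, 0L, 1L, 2L, 3L)

# The 21 block features consumed by the classifier.
FEATURE_NAMES <- c(paste0("entropy_", IMU_CHANNELS),
                   paste0("mean_", IMU_CHANNELS),
                   paste0("var_", IMU_CHANNELS),
                   paste0("xcorr_", c("x", "y", "z")))

STATE_NAMES <- c("rest", "gait", "functional")
# FAABOS code emitted by each generator state: rest -> 0 (no activity),
# gait -> 1 (nonfunctional arm swing), functional -> 3 (task-related).
STATE_CODES <- c(rest = 0L, gait = 1L, functional = 3L)
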