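# Field constants used across modules (all distances in micrometres, times in
# seconds). These operationalize the measurement rules for chick sensory axon
# timelapse data acquired at 3 s/frame and 0.12 um/pixel.

# Minimum edge-to-edge separation (5 pixels at 0.12 um) for a completed fission.
MIN_FISSION_SEPARATION_UM <- 0.6

# Per-frame leading-end displacement below this is not detectable movement
# (2 pixels of localization jitter).
DETECTABLE_MOVEMENT_UM <- 0.24

# A pause of at least this duration terminates a run.
RUN_TERMINATING_PAUSE_S <- 6

# Net excursion beyond this classifies a mitochondrion as transported.
TRANSPORT_THRESHOLD_UM <- 1.0

# Axonal projections strictly longer than this are collateral branches.
BRANCH_LENGTH_UM <- 10

# FRAP traces are included only if bleached to at most this fraction of the
# pre-bleach intensity (90% bleach).
FRAP_MAX_POSTBLEACH_FRACTION <- 0.1

# Smallest resolvable mitochondrion: 2 pixels.
MIN_SEGMENT_PIXELS <- 2
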