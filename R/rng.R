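# Deterministic named RNG substreams.
#
# Each sampling step of a simulation runs under a seed derived from the base
# seed and a stream name, so the same step always sees the same stream and
# changing e.g. nCells does not perturb the peak-mean draw.

# polynomial string hash folded into [0, 2^31 - 2]; stays in exact-double range
.streamSeed <- function(seed, stream) {
    h <- 0
    for (ch in utf8ToInt(stream))
        h <- (h * 131 + ch) %% 1000000007
    as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483646)
}

.withStream <- function(seed, stream, code) {
    withr::with_seed(.streamSeed(seed, stream), code)
}
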