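# p-values are reported on the raw scale but floored at the smallest
# positive representable double so downstream log transforms stay finite.
p_floor <- function(p) {
  pmax(p, .Machine$double.xmin)
}

# Deterministic per-replicate seed stream: counter-based spawning from a
# master seed, so replicate i is reproducible independently of how many
# replicates ran before it (and across process restarts). Kept below 2^31.
spawn_seed <- function(master, i) {
  as.integer(((as.double(master) %% 65011 + 1) * 30011 + as.double(i) * 7) %% 2147483587)
}

set_rep_seed <- function(master, i) {
  set.seed(spawn_seed(master, i))
}
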