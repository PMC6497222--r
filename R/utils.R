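# Seed the RNG for the calling frame, restoring the caller's stream on exit.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
}

# Render a double so that as.numeric() recovers it bit-exactly, preferring
# the shortest of 15/16/17 significant digits.
fmt_num <- function(x) {
  vapply(x, function(v) {
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}
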