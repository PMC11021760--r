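# deterministic integer sub-seed derived from a base seed and a stream tag
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  s <- 0
  for (ch in utf8ToInt(tag)) s <- (s * 31 + ch) %% 2147480009
  as.integer(s)
}
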