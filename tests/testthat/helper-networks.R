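# shared fixtures built in code

# the 16-row TFL1 automaton as drawn in the source model: 4 inputs, output 1
# iff LFY = 0, EMF1 = 1, AP1 = 0 (AP2 is a fully redundant input)
tfl1_lut <- function() {
  outs <- vapply(0:15, function(r) {
    b <- decode_config(r, 4)  # AP2, LFY, EMF1, AP1 (MSB first)
    as.integer(b[2] == 0L && b[3] == 1L && b[4] == 0L)
  }, 0L)
  lookup_table("TFL1", c("AP2", "LFY", "EMF1", "AP1"), outs)
}

random_lut <- function(k, name = "f") {
  repeat {
    outs <- sample(0:1, 2^k, replace = TRUE)
    if (length(unique(outs)) > 1L || k == 0L) break  # avoid trivial constants
  }
  lookup_table(name, paste0("in", seq_len(max(k, 0))), outs)
}

# two free identity bits: four fixed points
two_bit_net <- function() {
  boolean_network(list(lut_identity(name = "a", inputs = "a"),
                       lut_identity(name = "b", inputs = "b")))
}

schema_strings <- function(schemas) {
  sort(unname(vapply(schemas, function(s)
    paste0(paste(s$pattern, collapse = ""), ">", s$output), "")))
}
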