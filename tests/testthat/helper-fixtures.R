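# Shared fixtures built in code.

# mechanism with SI = 1 + ks/ki and MM substrate turnover
make_rates <- function(si = 9.49, k_on = 1e6, k_off = 0, k_i = 0.1,
                       kcat = 50, Km = 0.93e-3) {
  rate_constants(k_on = k_on, k_off = k_off, k_i = k_i,
                 k_s = (si - 1) * k_i, kcat = kcat, Km = Km)
}

# a 400-residue sequence over an alanine-free alphabet with the hinge
# motif ATAATA spliced at 346-351
make_hinge_fixture <- function(seed = 42) {
  set.seed(seed)
  alphabet <- setdiff(c("R", "N", "D", "C", "E", "Q", "H", "I", "L", "K",
                        "M", "F", "P", "W", "Y", "V"), "A")
  chars <- sample(alphabet, 400, replace = TRUE)
  chars[346:351] <- strsplit("ATAATA", "")[[1]]
  serpin_sequence("synthetic-hinge", paste(chars, collapse = ""))
}

identity_alignment <- function(n) data.frame(ref = 1:n, query = 1:n)

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
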