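# Shared fixtures, built in code once per test run.

tw <- build_world(1L)

# a 3-copy strain exercising several allele classes
tw_strain3 <- simulate_strain(tw, 3L, list(
  c(cidA = "cidA_IV(α/1)", cidB = "cidB_IV(a/1)"),
  c(cidA = "cidA_IV(δ/1)", cidB = "cidB_IV(a/2)"),
  c(cidA = "cidA_IV(β/2)", cidB = "cidB_IV(b/3)")), seed = 11L)

# strain whose 6 cidA / 4 cidB copies are all distinct variants
tw_strain6 <- simulate_strain(tw, 6L, list(
  c(cidA = "cidA_IV(α/1)", cidB = "cidB_IV(a/1)"),
  c(cidA = "cidA_IV(β/1)", cidB = "cidB_IV(a/2)"),
  c(cidA = "cidA_IV(γ/2)", cidB = "cidB_IV(b/1)"),
  c(cidA = "cidA_IV(δ/1)", cidB = "cidB_IV(b/3)"),
  c(cidA = "cidA_IV(α/2)", cidB = "cidB_IV(a/1)"),
  c(cidA = "cidA_IV(δ/2)", cidB = "cidB_IV(a/2)")), seed = 13L)

random_seqs <- function(n, len, seed = 99L) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
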