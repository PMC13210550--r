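# Shared fixtures: all built in code at test time.

# single-indicator null trial spec (no planted effects)
null_spec_1ind <- function(residual_sd = 1, baseline = 10,
                           n_blocks = 4) {
  effect_spec(genotypes = paste0("G", 1:5), years = paste0("Y", 1:3),
              n_blocks = n_blocks, baseline = c(y = baseline),
              residual_sd = residual_sd)
}

# fast direct null one-way layout: k groups of n
null_groups <- function(k = 5, n = 4) {
  data.frame(g = factor(rep(paste0("g", seq_len(k)), each = n)),
             y = rnorm(k * n))
}

# profile-level trial with two planted genotype groups separated by
# `sep` residual SDs on every indicator
two_group_spec <- function(sep = 5) {
  spec <- default_effect_spec(effect_scale = 0)
  g_eff <- matrix(0, 5, 15,
                  dimnames = list(spec$genotypes, spec$indicators))
  g_eff[c("3-12", "4-4"), ] <-
    rep(sep * spec$residual_sd, each = 2)
  effect_spec(spec$genotypes, spec$years, spec$n_blocks,
              baseline = spec$baseline, genotype_effects = g_eff,
              block_sd = 0, residual_sd = spec$residual_sd)
}
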