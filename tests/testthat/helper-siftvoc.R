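# Shared test helpers: independent oracles and small builders.

# Brute-force isotopologue oracle: enumerate all 2^n_cl heavy/light
# labelings of the chlorine atoms and bin by heavy count. Independent of
# the binomial closed form used by chlorine_envelope().
brute_force_envelope <- function(n_cl, p_heavy) {
  if (n_cl == 0) return(1)
  labelings <- expand.grid(rep(list(c(0L, 1L)), n_cl))
  heavy <- rowSums(labelings)
  prob <- apply(labelings, 1, function(z)
    prod(ifelse(z == 1L, p_heavy, 1 - p_heavy)))
  as.numeric(tapply(prob, factor(heavy, levels = 0:n_cl), sum))
}

# A headspace sample built from the default profile of one study cell.
profile_sample <- function(group, condition, replicate = 1L) {
  prof <- default_group_profiles()
  p <- prof[prof$group == group & prof$condition == condition, ]
  headspace_sample(stats::setNames(p$mean_mg_per_L, p$compound),
                   sample_id = sprintf("%s-%s-%d", group, condition,
                                       replicate),
                   group = group, condition = condition,
                   replicate = replicate)
}

# Reference count triplets (experimental rows only, counts present).
reference_triplets <- function() {
  ref <- reference_chcl2_counts()
  ref[!is.na(ref$mz83), ]
}
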