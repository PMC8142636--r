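fixture_harmonized <- function(outcome = c("pd_aao", "pd")) {
  outcome <- match.arg(outcome)
  paths <- vitc_pd_example()
  harmonize(read_associations(paths$exposure),
            read_associations(paths[[outcome]]))
}

fixture_exposure <- function() read_associations(vitc_pd_example()$exposure)

# build a harmonized set directly, bypassing file IO
make_hset <- function(beta_exp, beta_out, se_out,
                      se_exp = rep(0.01, length(beta_exp)),
                      snp = sprintf("v%02d", seq_along(beta_exp))) {
  h <- data.frame(snp = snp, ea = "A", nea = "G",
                  beta_exp = beta_exp, se_exp = se_exp,
                  beta_out = beta_out, se_out = se_out,
                  eaf_exp = 0.5, eaf_out = 0.5,
                  flipped = FALSE, palindromic = FALSE,
                  stringsAsFactors = FALSE)
  attr(h, "exposure_label") <- "toy_exposure"
  attr(h, "outcome_label") <- "toy_outcome"
  attr(h, "dropped") <- data.frame(snp = character(0), reason = character(0),
                                   stringsAsFactors = FALSE)
  class(h) <- c("harmonized_set", class(h))
  h
}

rand_hset <- function(k, seed) {
  set.seed(seed)
  make_hset(beta_exp = runif(k, 0.05, 0.4),
            beta_out = rnorm(k, 0, 0.3),
            se_out = runif(k, 0.05, 0.3),
            se_exp = runif(k, 0.005, 0.02))
}

toy_assoc <- function(snp, ea, nea, eaf, beta, se = 0.05, pval = 1e-9,
                      label = "toy") {
  as_associations(data.frame(snp = snp, ea = ea, nea = nea, eaf = eaf,
                             beta = beta, se = se, pval = pval,
                             stringsAsFactors = FALSE), label = label)
}
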