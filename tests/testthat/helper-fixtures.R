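# Shared fixtures: everything is generated in code at test time.

# small hand-sized dataset triple with one missing cell
tiny_dataset <- function() {
  vals <- matrix(c(10, 20, 30,
                   15, NA, 45), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("mA", "mB")))
  m <- metabolite_matrix(vals)
  s <- sample_annotation(data.frame(
    sample_id = c("s1", "s2", "s3"),
    group = c("CTRL", "MS", "MS"),
    status = c("NONE", "RELAPSE", "REMISSION"),
    edss = c(0, 5.5, 2), ocb = c(0, 1, 1),
    protein = c(30, 55, 48), wbc = c(1, 8, 3), igg_index = c(0.5, 1.1, 0.8)))
  a <- metabolite_annotation(data.frame(
    metabolite_id = c("mA", "mB"), name = c("mA", "mB"),
    chem_class = c("amino_acid", "fatty_acid"),
    fingerprint = c("1100", "0110"), compound_id = c("C1", "C2"),
    pathways = c("pw1", "pw1;pw2"), rpairs = c("mB", "mA")))
  list(matrix = m, samples = s, metabolites = a)
}

# random valid dataset of arbitrary size for round-trip / property tests
random_dataset <- function(n = 12, p = 6, seed = 1, missing = TRUE) {
  set.seed(seed)
  vals <- matrix(rlnorm(n * p, 8, 0.5), n, p,
                 dimnames = list(sprintf("s%02d", seq_len(n)),
                                 sprintf("met%02d", seq_len(p))))
  if (missing) vals[sample(length(vals), ceiling(n * p / 10))] <- NA
  grp <- sample(c("CTRL", "MS", "NMOSD", "ITM"), n, replace = TRUE)
  grp[1:2] <- c("CTRL", "MS")  # both tokens always present
  st <- ifelse(grp == "CTRL", "NONE",
               sample(c("REMISSION", "RELAPSE"), n, replace = TRUE))
  list(matrix = metabolite_matrix(vals),
       samples = sample_annotation(data.frame(
         sample_id = rownames(vals), group = grp, status = st,
         edss = ifelse(grp == "CTRL", 0, sample(seq(0, 10, 0.5), n, TRUE)),
         ocb = rbinom(n, 1, 0.4), protein = runif(n, 20, 80),
         wbc = rpois(n, 4), igg_index = runif(n, 0.3, 1.5))),
       metabolites = metabolite_annotation(data.frame(
         metabolite_id = colnames(vals), name = colnames(vals),
         chem_class = sample(c("sugar", "amino_acid", "fatty_acid"), p, TRUE),
         fingerprint = vapply(seq_len(p), function(i)
           paste(rbinom(16, 1, 0.4), collapse = ""), ""),
         compound_id = sprintf("C%03d", seq_len(p)),
         pathways = "toy", rpairs = NA)))
}

# default-design cohort taken through the standard preprocessing chain
preprocessed_cohort <- function(seed = 1) {
  cohort <- generate_cohort(reference_design(seed = seed))
  norm <- sum_normalize(cohort$matrix)
  filt <- occurrence_filter(norm, cohort$samples)
  imp <- impute_missing(filt)
  sc <- autoscale(imp)
  list(cohort = cohort, normalized = norm, imputed = imp,
       scaled = sc$matrix, state = sc$state)
}

# random scaled matrix + 2-class labels for latent-model contracts
random_two_class <- function(n = 30, p = 8, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p,
                    dimnames = list(sprintf("r%03d", seq_len(n)),
                                    sprintf("v%02d", seq_len(p)))))
  labels <- rep(c("A", "B"), length.out = n)
  list(X = X, labels = labels)
}
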