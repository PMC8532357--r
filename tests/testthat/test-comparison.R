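fake_set <- function(strain, values, reaction_ids, time_h = 24) {
  vinoflux:::new_sample_set(
    matrix(values, ncol = length(reaction_ids), byrow = FALSE,
           dimnames = list(NULL, reaction_ids)),
    reaction_ids, strain, time_h, sampler_config(n_samples = 1))
}

median_table_of <- function(...) {
  tbl <- tibble::tribble(...)
  class(tbl) <- c("median_table", class(tbl))
  tbl
}

test_that("reaction medians are columnwise sample medians", {
  s <- fake_set("A", c(1, 2, 3, 5, 5, 5), c("r1", "r2"))
  mt <- reaction_medians(list(s))
  expect_equal(mt$median_flux[mt$reaction_id == "r1"], 2)
  expect_equal(mt$median_flux[mt$reaction_id == "r2"], 5)

  ss <- achr_sample(chain_system(), sampler_config(n_samples = 10000,
                                                   seed = 9),
                    strain = "A")
  mt2 <- reaction_medians(list(ss))
  expect_lt(abs(mt2$median_flux[mt2$reaction_id == "R1"] - 5), 0.2)

  mismatched <- fake_set("B", 1:4, c("rX", "rY"))
  expect_error(reaction_medians(list(s, mismatched)), "same reaction ids")
})

test_that("absolute ranking orders by median range with lexicographic ties", {
  tbl <- median_table_of(
    ~strain, ~time_h, ~reaction_id, ~median_flux,
    "A", 24, "r1", 2,
    "A", 24, "r2", 5,
    "B", 24, "r1", 2,
    "B", 24, "r2", 1)
  rk <- rank_absolute_median_difference(tbl, k = 1)
  expect_equal(rk$reaction_id, "r2")
  expect_equal(rk$spread, 4)
  expect_equal(rk$A, 5)
  expect_equal(rk$B, 1)

  # identical strains: every spread 0, ties broken lexicographically
  tied <- median_table_of(
    ~strain, ~time_h, ~reaction_id, ~median_flux,
    "A", 24, "zz", 1, "A", 24, "aa", 1, "A", 24, "mm", 1,
    "B", 24, "zz", 1, "B", 24, "aa", 1, "B", 24, "mm", 1)
  rk2 <- rank_absolute_median_difference(tied, k = 2)
  expect_equal(rk2$reaction_id, c("aa", "mm"))
  expect_equal(rk2$spread, c(0, 0))

  # spread is shift-invariant
  shifted <- tbl
  shifted$median_flux <- shifted$median_flux +
    ifelse(shifted$reaction_id == "r2", 100, 0)
  expect_equal(rank_absolute_median_difference(shifted, 2)$spread,
               rank_absolute_median_difference(tbl, 2)$spread)

  # k = all reactions returns a permutation of the reaction ids
  rk3 <- rank_absolute_median_difference(tbl, k = 99)
  expect_setequal(rk3$reaction_id, c("r1", "r2"))

  expect_error(
    rank_absolute_median_difference(dplyr::filter(tbl, strain == "A")),
    "2 strains")
})

test_that("percent ranking excludes miniscule fluxes and scales by the grand median", {
  tbl <- median_table_of(
    ~strain, ~time_h, ~reaction_id, ~median_flux,
    "A", 24, "tiny", 1e-14,
    "A", 24, "real", 1,
    "A", 24, "flat", 3,
    "B", 24, "tiny", 3e-14,
    "B", 24, "real", 2,
    "B", 24, "flat", 3)
  rk <- rank_percent_median_difference(tbl, k = 10)
  expect_false("tiny" %in% rk$reaction_id)
  # range 1 over |grand median| 1.5
  expect_equal(rk$percent_spread[rk$reaction_id == "real"], 100 / 1.5)
  expect_equal(rk$percent_spread[rk$reaction_id == "flat"], 0)
})

test_that("ranking annotation joins model gene and subsystem columns", {
  m <- build_toy_wine_network()
  tbl <- median_table_of(
    ~strain, ~time_h, ~reaction_id, ~median_flux,
    "A", 24, "PDC", 1, "B", 24, "PDC", 3,
    "A", 24, "HXK", 2, "B", 24, "HXK", 2)
  rk <- annotate_ranking(rank_absolute_median_difference(tbl, 2), m)
  expect_equal(rk$gene_association[rk$reaction_id == "PDC"], "TOY_PDC1")
  expect_match(rk$subsystem[rk$reaction_id == "PDC"], "Ehrlich")
})

test_that("PCA satisfies the squared-cosine and variance identities", {
  set.seed(4)
  X <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(paste0("o", 1:8), paste0("v", 1:5)))
  p <- pca_with_cos2(X, scale = TRUE)
  # per-variable cos2 sums to 1 over all components (scaled PCA)
  expect_equal(unname(rowSums(p$cos2_variables)), rep(1, 5),
               tolerance = 1e-9)
  expect_true(all(p$cos2_variables >= 0 & p$cos2_variables <= 1 + 1e-12))
  # variance fractions: nonnegative, nonincreasing, summing to 1
  ve <- p$variance_explained
  expect_true(all(ve >= 0))
  expect_true(all(diff(ve) <= 1e-12))
  expect_equal(sum(ve), 1, tolerance = 1e-12)
  # observation cos2 rows sum to 1
  expect_equal(unname(rowSums(p$cos2_individuals)), rep(1, 8),
               tolerance = 1e-9)

  # identical observations coincide in score space
  X2 <- X; X2[2, ] <- X2[1, ]
  p2 <- pca_with_cos2(X2, scale = TRUE)
  expect_lt(max(abs(p2$scores[1, ] - p2$scores[2, ])), 1e-9)
})

test_that("PCA recovers planted low-rank structure", {
  set.seed(8)
  n_obs <- 12; n_var <- 9
  f <- matrix(rnorm(n_obs * 2), n_obs, 2)
  load <- matrix(rnorm(2 * n_var), 2, n_var)
  X <- f %*% load + matrix(rnorm(n_obs * n_var, sd = 0.01), n_obs, n_var)
  colnames(X) <- paste0("v", seq_len(n_var))
  p <- pca_with_cos2(X, scale = TRUE)
  expect_gt(sum(p$variance_explained[1:2]), 0.95)
})

test_that("PCA rejects constant variables when scaling", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(0, 1, 0))
  expect_error(pca_with_cos2(X, scale = TRUE), "b")
  expect_silent(pca_with_cos2(X, scale = FALSE))
})

test_that("clustering groups proportional strains at zero height", {
  tbl <- median_table_of(
    ~strain, ~time_h, ~reaction_id, ~median_flux,
    "A", 24, "r1", 1, "A", 24, "r2", 2, "A", 24, "r3", 5,
    "B", 24, "r1", 2, "B", 24, "r2", 4, "B", 24, "r3", 10,
    "C", 24, "r1", 5, "C", 24, "r2", 1, "C", 24, "r3", 0)
  cl <- cluster_strains(tbl)
  expect_equal(cl$correlation["A", "B"], 1)
  expect_equal(first_merge(cl), c("A", "B"))
  expect_lt(cl$hclust$height[1], 1e-12)
  # merge heights nondecreasing
  expect_true(all(diff(cl$hclust$height) >= -1e-12))

  # invariance to positive rescaling of a strain vector
  tbl2 <- tbl
  tbl2$median_flux[tbl2$strain == "C"] <-
    tbl2$median_flux[tbl2$strain == "C"] * 7
  cl2 <- cluster_strains(tbl2)
  expect_equal(cl2$correlation, cl$correlation)

  # two strains: single merge, symmetric 2x2 correlation
  two <- dplyr::filter(tbl, strain %in% c("A", "C"))
  class(two) <- class(tbl)
  cl3 <- cluster_strains(two)
  expect_equal(dim(cl3$correlation), c(2, 2))
  expect_equal(cl3$correlation, t(cl3$correlation))
  expect_equal(nrow(cl3$hclust$merge), 1)

  expect_error(cluster_strains(tbl, subset = c("r1", "nope")), "nope")
})

test_that("cluster results export to Newick and tidy merge tables", {
  tbl <- median_table_of(
    ~strain, ~time_h, ~reaction_id, ~median_flux,
    "A", 24, "r1", 1, "A", 24, "r2", 2, "A", 24, "r3", 5,
    "B", 24, "r1", 1.1, "B", 24, "r2", 2.2, "B", 24, "r3", 4.9,
    "C", 24, "r1", 5, "C", 24, "r2", 1, "C", 24, "r3", 0)
  cl <- cluster_strains(tbl)
  nwk <- cluster_newick(cl)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))

  td <- tidy(cl)
  expect_equal(nrow(td), 2)
  expect_equal(td$members[[nrow(td)]], c("A", "B", "C"))
})

test_that("histograms normalize per strain on a shared range", {
  s1 <- achr_sample(chain_system(), sampler_config(n_samples = 10000,
                                                   seed = 21),
                    strain = "A")
  s2 <- achr_sample(chain_system(), sampler_config(n_samples = 10000,
                                                   seed = 22),
                    strain = "B")
  h <- histogram_report(list(s1, s2), c("R1", "EX_A"), bins = 10)
  sums <- dplyr::summarise(
    dplyr::group_by(h, reaction_id, strain),
    total = sum(rel_freq), .groups = "drop")
  expect_equal(sums$total, rep(1, 4), tolerance = 1e-12)

  # uniform marginal: occupied-bin frequencies are near-flat
  hr <- dplyr::filter(h, reaction_id == "R1", strain == "A",
                      rel_freq > 0)
  expect_lt(max(hr$rel_freq) / min(hr$rel_freq), 1.5)

  # a fixed reaction occupies a single bin
  ssx <- achr_sample(simplex_system(), sampler_config(n_samples = 500,
                                                      seed = 5),
                     strain = "A")
  hfix <- histogram_report(list(ssx), "IN", bins = 10)
  expect_equal(sum(hfix$rel_freq > 0), 1)

  expect_error(histogram_report(list(s1), "nope"), "unknown reaction")
})
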