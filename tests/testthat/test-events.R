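test_that("build_mask gates inclusively and never passes missing values", {
  d <- parse_dataset("g1 A 0.4 0.6\ng1 B NA 0.5")
  expect_true(all(build_mask(d)[, "A", ]))        # default: all observed pass
  m <- build_mask(d, list(A = c(0.5, 1.0)))
  expect_equal(unname(m["g1", "A", ]), c(FALSE, TRUE))
  expect_false(build_mask(d)["g1", "B", 1])       # missing never passes
  expect_error(build_mask(d, list(Z = c(0, 1))),
               class = "phenoarc_key_error")
  # boundary values are inside the interval (inclusive both ends)
  m2 <- build_mask(d, list(A = c(0.4, 0.6)))
  expect_true(all(m2["g1", "A", ]))
})

test_that("quartile thresholds match the sort-based percentile oracle", {
  d <- parse_dataset(paste(sprintf("g%d A %d %d", 1:4, 1:4, 5:8),
                           collapse = "\n"))
  lo <- quartile_thresholds(d, "lower")
  hi <- quartile_thresholds(d, "upper")
  expect_equal(lo["A", "hi"], oracle_quantile(1:8, 0.25))
  expect_equal(hi["A", "lo"], oracle_quantile(1:8, 0.75))

  set.seed(7)
  for (i in 1:100) {
    v <- round(runif(sample(4:40, 1), -3, 3), 4)
    d1 <- pheno_dataset(data.frame(gene = sprintf("g%d", seq_along(v)),
                                   phenotype = "P"),
                        matrix(v, ncol = 1))
    expect_equal(quartile_thresholds(d1, "lower")["P", "hi"],
                 oracle_quantile(v, 0.25))
    expect_equal(quartile_thresholds(d1, "upper")["P", "lo"],
                 oracle_quantile(v, 0.75))
    # lower-side pass fraction is >= 0.25 and minimal over observed cuts
    q1 <- oracle_quantile(v, 0.25)
    frac <- mean(v <= q1)
    expect_gte(frac, 0.25)
    smaller_cuts <- sort(unique(v))[sapply(sort(unique(v)), function(cut)
      mean(v <= cut) >= 0.25)]
    expect_equal(frac, min(sapply(smaller_cuts, function(cut) mean(v <= cut))))
  }

  # degenerate distributions
  dc <- parse_dataset("g1 A 2 2\ng2 A 2 2")
  expect_equal(quartile_thresholds(dc, "lower")["A", "hi"], 2)
  expect_equal(quartile_thresholds(dc, "upper")["A", "lo"], 2)
  expect_true(all(build_mask(dc, quartile_thresholds(dc, "lower"))[, "A", ]))
  d1 <- parse_dataset("g1 A 5")
  expect_equal(quartile_thresholds(d1, "lower")["A", "hi"], 5)
  dempty <- parse_dataset("g1 A NA NA")
  expect_error(quartile_thresholds(dempty, "lower"),
               class = "phenoarc_value_error")
})

test_that("co-occurrence derivation matches the brute-force triple loop", {
  # planted single pattern
  prof <- matrix(c("A", "B", NA), 1, 3, dimnames = list("g1", NULL))
  d <- dataset_from_profiles(prof, c("A", "B"))
  mask <- build_mask(d, list(A = c(0.5, 1), B = c(0.5, 1)))
  cs <- derive_cooccurrence(mask, lags = 1L)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$source, "A"); expect_equal(cs$target, "B")
  expect_equal(cs$t_source, 1L); expect_equal(cs$t_target, 2L)
  expect_equal(cs$genes[[1L]], "g1")

  # aggregation across genes
  prof3 <- matrix(rep(c("A", "B", NA), each = 3), 3, 3,
                  dimnames = list(paste0("g", 1:3), NULL))
  d3 <- dataset_from_profiles(prof3, c("A", "B"))
  cs3 <- derive_cooccurrence(build_mask(d3, list(A = c(0.5, 1), B = c(0.5, 1))), 1L)
  expect_equal(cs3$weight, 3L)

  expect_error(derive_cooccurrence(build_mask(d3), lags = 5L),
               class = "phenoarc_value_error")

  # random-fixture conservation against the independent recount
  set.seed(11)
  for (i in 1:10) {
    mask <- array(runif(20 * 5 * 10) < 0.35, dim = c(20, 5, 10),
                  dimnames = list(sprintf("g%02d", 1:20),
                                  sprintf("p%d", 1:5), NULL))
    for (lags in list(0L, 1L, c(0L, 2L))) {
      got <- connections_key(derive_cooccurrence(mask, lags))
      want <- brute_cooccurrence(mask, lags)
      expect_equal(length(got), nrow(want))
      expect_equal(unname(got[want$key]), want$weight)
    }
  }
})

test_that("with no thresholds every phenotype pair is interconnected", {
  d <- random_dataset(n_genes = 6, n_phen = 4, n_time = 5, p_missing = 0,
                      complete_pairs = TRUE)
  cs <- derive_cooccurrence(build_mask(d), lags = 0L)
  P <- 4; n <- 5
  expect_equal(nrow(cs), n * P * (P - 1) / 2)
  expect_true(all(cs$weight == 6L))
})

test_that("tightening thresholds never increases connection weights", {
  set.seed(3)
  d <- random_dataset(n_genes = 10, n_phen = 3, n_time = 6, p_missing = 0,
                      complete_pairs = TRUE)
  wide <- derive_cooccurrence(build_mask(d, list(ph1 = c(0.1, 0.9))), 0:1)
  tight <- derive_cooccurrence(build_mask(d, list(ph1 = c(0.2, 0.8))), 0:1)
  kw <- connections_key(wide); kt <- connections_key(tight)
  expect_true(all(names(kt) %in% names(kw)))
  expect_true(all(kt <= kw[names(kt)]))
})

test_that("prominence takes the arg-max with first-phenotype tie-break", {
  d <- parse_dataset("g1 A 0.9 0.5 0.2\ng1 B 0.1 0.5 0.8")
  prof <- derive_prominence(d)
  expect_equal(unname(prof["g1", ]), c("A", "A", "B"))  # tie at t=2 -> A
  # thresholds can empty a time point
  prof2 <- derive_prominence(d, list(A = c(0.85, 1), B = c(0.85, 1)))
  expect_equal(unname(prof2["g1", ]), c("A", NA, NA))
  # all-missing time point gives none
  dm <- parse_dataset("g1 A NA 0.5\ng1 B NA 0.2")
  expect_equal(unname(derive_prominence(dm)["g1", ]), c(NA, "A"))
})

test_that("transitions link consecutive differing prominent phenotypes", {
  prof <- matrix(c("A", "A", "B"), 1, 3, dimnames = list("g1", NULL))
  d <- dataset_from_profiles(prof, c("A", "B"))
  tr <- derive_transitions(derive_prominence(d))
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$t_source, 2L); expect_equal(tr$t_target, 3L)
  expect_true(all(tr$directed))

  # a gap breaks the chain
  profg <- matrix(c("A", NA, "B"), 1, 3, dimnames = list("g1", NULL))
  dg <- dataset_from_profiles(profg, c("A", "B"))
  expect_equal(nrow(derive_transitions(derive_prominence(dg))), 0L)

  # no self records, all lags exactly 1
  set.seed(5)
  d3 <- random_dataset(n_genes = 12, n_phen = 4, n_time = 8,
                       p_missing = 0.15, complete_pairs = TRUE)
  tr3 <- derive_transitions(derive_prominence(d3))
  expect_true(all(tr3$source != tr3$target))
  expect_true(all(tr3$t_target - tr3$t_source == 1L))
  # include_self emits the unchanged records too
  trs <- derive_transitions(derive_prominence(d3), include_self = TRUE)
  expect_gte(nrow(trs), nrow(tr3))
})

test_that("filter_connections applies touch/intersect/window/lag semantics", {
  cs <- connection_set(
    source = c("A", "A", "B"), target = c("B", "C", "C"),
    t_source = c(1L, 2L, 3L), t_target = c(2L, 4L, 4L),
    genes = list(c("g1", "g2"), "g2", "g3"),
    directed = c(TRUE, TRUE, TRUE))
  # touch semantics on phenotype subset
  f <- filter_connections(cs, phenotype_subset = "B")
  expect_equal(nrow(f), 2L)
  # gene intersection drops emptied records and recomputes weight
  f2 <- filter_connections(cs, gene_subset = "g2")
  expect_equal(nrow(f2), 2L)
  expect_true(all(f2$weight == 1L))
  expect_equal(nrow(filter_connections(cs, gene_subset = "g9")), 0L)
  # lag cap
  f3 <- filter_connections(cs, max_lag = 1L)
  expect_equal(nrow(f3), 2L)
  # window keeps records fully inside
  f4 <- filter_connections(cs, time_window = c(1L, 2L))
  expect_equal(nrow(f4), 1L)
  # validation against a dataset universe
  d <- parse_dataset("g1 A 1 2")
  expect_error(filter_connections(cs, gene_subset = "nope", dataset = d),
               class = "phenoarc_key_error")
  expect_error(filter_connections(cs, phenotype_subset = "Z", dataset = d),
               class = "phenoarc_key_error")
})

test_that("pair-specific genes are those in exactly one pair's set", {
  cs <- connection_set(
    source = c("A", "A"), target = c("B", "C"),
    t_source = c(1L, 1L), t_target = c(1L, 1L),
    genes = list(c("g1", "g2"), "g2"), directed = c(FALSE, FALSE))
  sp <- pair_specific_genes(cs)
  expect_equal(sp[["A|B"]], "g1")
  expect_equal(sp[["A|C"]], character(0))
  # single pair: everything specific
  one <- connection_set("A", "B", 1L, 1L, list(c("g1", "g2")), FALSE)
  expect_equal(pair_specific_genes(one)[["A|B"]], c("g1", "g2"))
  # identical gene sets on two pairs: both empty
  same <- connection_set(c("A", "A"), c("B", "C"), c(1L, 1L), c(1L, 1L),
                         list("g1", "g1"), c(FALSE, FALSE))
  expect_true(all(lengths(pair_specific_genes(same)) == 0L))
  expect_error(pair_specific_genes(connection_set()),
               class = "phenoarc_value_error")
})
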