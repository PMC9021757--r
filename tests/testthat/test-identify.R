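# Best match, best close match, and leave-one-out top-hit identification.

# hand-built distance structure for precise classification checks
toy_dm <- function(d, labels) {
  valid <- !is.na(d); diag(valid) <- TRUE; diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  dimnames(valid) <- dimnames(d)
  structure(list(labels = labels, d = d, valid = valid,
                 n_sites = matrix(100L, nrow(d), nrow(d),
                                  dimnames = dimnames(d))),
            class = "k2p_matrix")
}

test_that("best match classifies by the species of the nearest neighbours", {
  labels <- c("q", "a2", "b1", "c1")
  samples <- samples_table(labels, c("sp_a", "sp_a", "sp_b", "sp_c"))
  d <- matrix(c(0, .01, .05, .07,
                .01, 0, .06, .08,
                .05, .06, 0, .02,
                .07, .08, .02, 0), 4, byrow = TRUE)
  rep <- best_match(toy_dm(d, labels), samples)
  pq <- rep$per_query
  expect_equal(pq$status[pq$query == "q"], "success")
  # c1 is a singleton: its nearest neighbour can never be conspecific
  expect_equal(pq$status[pq$query == "c1"], "failure")
  expect_true(pq$is_singleton[pq$query == "c1"])
  expect_equal(rep$counts$success + rep$counts$ambiguous +
               rep$counts$failure + rep$counts$unidentified, rep$n_queries)
})

test_that("exact distance ties across species are ambiguous", {
  labels <- c("q", "a2", "b1")
  samples <- samples_table(labels, c("sp_a", "sp_a", "sp_b"))
  d <- matrix(c(0, .02, .02,
                .02, 0, .03,
                .02, .03, 0), 3, byrow = TRUE)
  rep <- best_match(toy_dm(d, labels), samples)
  expect_equal(rep$per_query$status[rep$per_query$query == "q"], "ambiguous")
  expect_equal(rep$per_query$nearest[rep$per_query$query == "q"], "a2,b1")
})

test_that("outgroups are excluded from queries and references", {
  labels <- c("a1", "a2", "og")
  samples <- samples_table(labels, c("sp_a", "sp_a", "out_x"),
                           outgroup = c(FALSE, FALSE, TRUE))
  # outgroup would be the nearest neighbour of a1 if it were eligible
  d <- matrix(c(0, .05, .001,
                .05, 0, .06,
                .001, .06, 0), 3, byrow = TRUE)
  rep <- best_match(toy_dm(d, labels), samples)
  expect_equal(rep$n_queries, 2)
  expect_true(all(rep$per_query$status == "success"))
})

test_that("intraspecific threshold interpolates order statistics", {
  mk_gp <- function(x) structure(
    list(intra = data.frame(species = rep("s_a", length(x)), distance = x),
         inter = data.frame(species1 = character(), species2 = character(),
                            distance = numeric())),
    class = "gap_profile")
  x <- seq(0.001, 0.020, by = 0.001)
  expect_equal(intraspecific_threshold(mk_gp(x), 0.95),
               unname(stats::quantile(x, 0.95, type = 7)), tolerance = 1e-12)
  set.seed(8)
  y <- stats::runif(37, 0, 0.05)
  for (q in c(0.5, 0.9, 0.95))
    expect_equal(intraspecific_threshold(mk_gp(y), q),
                 unname(stats::quantile(y, q, type = 7)), tolerance = 1e-12)
  expect_equal(intraspecific_threshold(mk_gp(rep(0.004, 9)), 0.33), 0.004)
  expect_equal(intraspecific_threshold(mk_gp(y), 1.0), max(y))
  expect_error(intraspecific_threshold(mk_gp(numeric(0)), 0.95),
               class = "barcodegap_validation_error")
})

test_that("queries beyond the threshold are unidentified", {
  labels <- c("q", "a2", "b1")
  samples <- samples_table(labels, c("sp_a", "sp_a", "sp_b"))
  d <- matrix(c(0, .08, .09,
                .08, 0, .01,
                .09, .01, 0), 3, byrow = TRUE)
  rep <- best_close_match(toy_dm(d, labels), samples, threshold = 0.02)
  expect_equal(rep$per_query$status[rep$per_query$query == "q"], "unidentified")
  expect_equal(rep$per_query$status[rep$per_query$query == "a2"], "failure")
})

test_that("best close match with infinite threshold equals best match", {
  for (seed in 1:20) {
    res <- small_sim(seed, n_species = 6, ind = c(1, 4),
                     intra = 0.004, inter = 0.08)
    dm <- k2p_distance_matrix(res$dataset$loci$L1)
    bm <- best_match(dm, res$dataset$samples)
    bcm <- best_close_match(dm, res$dataset$samples, threshold = Inf)
    expect_identical(bm, bcm)
  }
})

test_that("statuses are invariant under strictly monotone distance transforms", {
  res <- small_sim(31, n_species = 6, ind = c(1, 3))
  dm <- k2p_distance_matrix(res$dataset$loci$L1)
  dm2 <- dm
  dm2$d <- sqrt(dm$d)  # strictly monotone on [0, Inf)
  r1 <- best_match(dm, res$dataset$samples)
  r2 <- best_match(dm2, res$dataset$samples)
  expect_identical(r1$per_query$status, r2$per_query$status)
  expect_identical(r1$per_query$nearest, r2$per_query$nearest)
})

test_that("unidentified count grows as the threshold tightens", {
  res <- small_sim(77, n_species = 8, ind = c(2, 3),
                   intra = 0.004, inter = 0.08)
  dm <- k2p_distance_matrix(res$dataset$loci$L1)
  grid <- c(0.05, 0.02, 0.01, 0.005, 0.001)
  un <- vapply(grid, function(th)
    best_close_match(dm, res$dataset$samples, th)$counts$unidentified,
    numeric(1))
  expect_true(all(diff(un) >= 0))
})

test_that("zero intraspecific divergence gives perfect non-singleton matching", {
  for (seed in 1:3) {
    p <- sim_params(8, c(1, 3), list(locus_spec("L1", 600)),
                    intra_depth = 0, inter_depth = 0.08, seed = seed)
    res <- build_dataset(p)
    dm <- k2p_distance_matrix(res$dataset$loci$L1)
    rep <- best_match(dm, res$dataset$samples)
    multi <- rep$per_query[!rep$per_query$is_singleton, ]
    expect_true(all(multi$status == "success"))
  }
})

test_that("top-hit discrimination requires exclusively conspecific top hits", {
  aln <- make_aln(c(a1 = "AAAAAAAAGG", a2 = "AAAAAAAAGC",
                    b1 = "GGGGAAAAGG", b2 = "GGGGAAAAGC"))
  samples <- samples_table(names(aln$seqs), c("sp_a", "sp_a", "sp_b", "sp_b"))
  rep <- top_hit_discrimination(aln, samples)
  expect_equal(rep$rate, 100)
  # identical twin sequences force both species to fail
  aln2 <- make_aln(c(a1 = "AAAAAAAAGG", a2 = "AAAAAAAAGG",
                     t1 = "AAAAAAAAGG", t2 = "AAAAAAAAGG",
                     b1 = "GGGGAAAAGG", b2 = "GGGGAAAAGC"))
  samples2 <- samples_table(names(aln2$seqs),
                            c("sp_a", "sp_a", "sp_t", "sp_t", "sp_b", "sp_b"))
  rep2 <- top_hit_discrimination(aln2, samples2)
  per <- rep2$per_species
  expect_false(per$success[per$species == "sp_a"])
  expect_false(per$success[per$species == "sp_t"])
  expect_true(per$success[per$species == "sp_b"])
})

test_that("top-hit and NJ discrimination agree on well-separated data", {
  res <- small_sim(91, n_species = 10, ind = c(2, 3),
                   intra = 0.002, inter = 0.12)
  aln <- res$dataset$loci$L1
  th <- top_hit_discrimination(aln, res$dataset$samples)
  tr <- bootstrap_support(aln, B = 100, seed = 6)
  nj <- species_discrimination(tr, res$dataset$samples, threshold = 0)
  expect_equal(th$rate, nj$rate)
  nj_fail <- nj$per_species$species[nj$per_species$status == "non-monophyletic"]
  th_fail <- th$per_species$species[!th$per_species$success]
  expect_setequal(nj_fail, th_fail)
})
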