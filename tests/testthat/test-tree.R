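# Neighbour joining, bootstrap support, monophyly-based discrimination.

test_that("three leaves solve the three-point equations exactly", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  expect_equal(ape::Ntip(tr), 3)
  cop <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(cop), unname(D), tolerance = 1e-12)
  # closed form: x_A = (3 + 4 - 5)/2 = 1, x_B = 2, x_C = 3
  tip_edges <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(sort(tip_edges), c(1, 2, 3), tolerance = 1e-12)
})

test_that("a four-leaf additive matrix is reproduced exactly", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(true)
  est <- nj_tree(D)
  expect_setequal(biparts_of(est), biparts_of(ape::unroot(true)))
  cop <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
  expect_equal(unname(cop), unname(D), tolerance = 1e-9)
})

test_that("NJ is consistent on random additive matrices (n <= 6)", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(4:6, 1)
    true <- rand_additive_tree(n)
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    expect_setequal(biparts_of(est), biparts_of(true))
    cop <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(unname(cop), unname(D), tolerance = 1e-9)
  }
})

test_that("NJ topology matches an established implementation on noisy input", {
  set.seed(33)
  for (rep in 1:5) {
    true <- rand_additive_tree(8)
    D <- ape::cophenetic.phylo(true)
    noise <- matrix(stats::runif(64, 0, 0.02), 8)
    Dn <- D + noise + t(noise); diag(Dn) <- 0
    est <- nj_tree(Dn)
    ref <- ape::nj(as.dist(Dn))
    expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ output is invariant under input label order", {
  set.seed(41)
  true <- rand_additive_tree(7)
  D <- ape::cophenetic.phylo(true)
  perm <- sample(7)
  est1 <- nj_tree(D)
  est2 <- nj_tree(D[perm, perm])
  expect_setequal(biparts_of(est1), biparts_of(est2))
  expect_equal(sum(est1$edge.length), sum(est2$edge.length), tolerance = 1e-9)
})

test_that("NJ rejects degenerate inputs", {
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               class = "barcodegap_validation_error")
  aln <- make_aln(c(a = "AAAA", b = "CCCC", c = "AAAA"))
  dm <- suppressWarnings(k2p_distance_matrix(aln))  # a-b saturated
  expect_error(nj_tree(dm), "invalid", class = "barcodegap_validation_error")
})

test_that("unanimous signal earns 100% support and B=1 gives {0,100}", {
  # every variable column is compatible with the split {a,b} | {c,d}
  seqs <- c(a = paste0(strrep("A", 10), strrep("T", 50)),
            b = paste0(strrep("A", 10), strrep("T", 50)),
            c = paste0(strrep("G", 10), strrep("T", 50)),
            d = paste0(strrep("G", 10), strrep("T", 40), strrep("C", 10)))
  aln <- make_aln(seqs)
  tr <- bootstrap_support(aln, B = 20, seed = 1)
  sup <- attr(tr, "support")
  expect_true(all(sup[!is.na(sup)] == 100))
  tr1 <- bootstrap_support(aln, B = 1, seed = 2)
  sup1 <- attr(tr1, "support")
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
})

test_that("bootstrap supports are reproducible for a fixed seed", {
  res <- small_sim(7, n_species = 6, ind = 2)
  aln <- res$dataset$loci$L1
  t1 <- bootstrap_support(aln, B = 50, seed = 99)
  t2 <- bootstrap_support(aln, B = 50, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  t3 <- bootstrap_support(aln, B = 50, seed = 100)
  expect_false(identical(attr(t1, "support"), attr(t3, "support")))
})

test_that("partitioned resampling stays within locus blocks", {
  # locus A's variable columns all support ab|cd; locus B is constant, so
  # every within-block resample is compatible with the same split
  seqs <- c(a = paste0(strrep("A", 10), strrep("T", 50)),
            b = paste0(strrep("A", 10), strrep("T", 50)),
            c = paste0(strrep("G", 10), strrep("T", 50)),
            d = paste0(strrep("G", 10), strrep("T", 50)))
  part <- data.frame(locus = c("A", "B"), start = c(1L, 41L), end = c(40L, 60L))
  aln <- locus_alignment("A+B", seqs, partition = part)
  tr <- bootstrap_support(aln, B = 25, seed = 3)
  sup <- attr(tr, "support")
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("monophyly statuses follow the tree exactly", {
  # perfect two-cherry tree: both species succeed
  tr <- ape::read.tree(text = "((a1:1,a2:1):2,(b1:1,b2:1):2);")
  samples <- samples_table(c("a1", "a2", "b1", "b2"),
                           c("sp_a", "sp_a", "sp_b", "sp_b"))
  rep <- species_discrimination(tr, samples, threshold = 0)
  expect_equal(rep$rate, 100)
  expect_equal(rep$n_evaluated, 2)
  # species split apart by an interloper fails
  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rep2 <- species_discrimination(tr2, samples, threshold = 0)
  expect_equal(rep2$n_success, 0)
  expect_true(all(rep2$per_species$status == "non-monophyletic"))
})

test_that("support threshold gates success and is monotone", {
  tr <- ape::read.tree(
    text = "((a1:1,a2:1)55:2,((b1:1,b2:1)70:1,c1:3)55:1);")
  samples <- samples_table(c("a1", "a2", "b1", "b2", "c1"),
                           c("sp_a", "sp_a", "sp_b", "sp_b", "sp_c"))
  r50 <- species_discrimination(tr, samples, threshold = 50)
  r60 <- species_discrimination(tr, samples, threshold = 60)
  r80 <- species_discrimination(tr, samples, threshold = 80)
  expect_equal(r50$n_success, 2)
  expect_equal(r60$n_success, 1)
  expect_equal(r60$per_species$status[r60$per_species$species == "sp_a"],
               "monophyletic-low-support")
  expect_equal(r80$n_success, 0)
  expect_true(r50$n_success >= r60$n_success && r60$n_success >= r80$n_success)
})

test_that("singleton policy controls the denominator", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):2,(b1:1,c1:1):2);")
  samples <- samples_table(c("a1", "a2", "b1", "c1"),
                           c("sp_a", "sp_a", "sp_b", "sp_c"))
  r_ex <- species_discrimination(tr, samples, threshold = 0, "exclude")
  expect_equal(r_ex$n_evaluated, 1)
  expect_equal(r_ex$rate, 100)
  r_fail <- species_discrimination(tr, samples, threshold = 0, "fail")
  expect_equal(r_fail$n_evaluated, 3)
  expect_equal(r_fail$n_success, 1)
  r_suc <- species_discrimination(tr, samples, threshold = 0, "succeed")
  expect_equal(r_suc$n_success, 3)
})

test_that("outgroups root the monophyly test and leave the denominator", {
  # without the outgroup constraint sp_a would be "monophyletic" via the
  # complement side; rooting by the outgroup must break it
  tr <- ape::read.tree(text = "(((a1:1,b1:1):1,a2:2):1,og:5);")
  samples <- samples_table(c("a1", "b1", "a2", "og"),
                           c("sp_a", "sp_b", "sp_a", "Lysimachia_vulgaris"),
                           outgroup = c(FALSE, FALSE, FALSE, TRUE))
  rep <- species_discrimination(tr, samples, threshold = 0)
  expect_equal(rep$per_species$status[rep$per_species$species == "sp_a"],
               "non-monophyletic")
  expect_false("Lysimachia_vulgaris" %in% rep$per_species$species)
})

test_that("monophyly decisions match an independent rooted-clade oracle", {
  set.seed(55)
  for (rep in 1:100) {
    n <- sample(6:12, 1)
    tr <- ape::rtree(n)  # rooted random tree
    # random species assignment over 2-4 species plus a designated outgroup tip
    tips <- tr$tip.label
    og <- tips[1]
    sp <- c("outgr_x", sample(paste0("sp_", letters[1:sample(2:4, 1)]),
                              n - 1, replace = TRUE))
    samples <- samples_table(tips, sp, outgroup = tips == og)
    mine <- species_discrimination(tr, samples, threshold = 0)
    rooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    for (s in unique(sp[-1])) {
      stips <- tips[sp == s]
      if (length(stips) < 2) next
      mrca <- ape::getMRCA(rooted, stips)
      desc <- ape::extract.clade(rooted, mrca)$tip.label
      oracle <- setequal(desc, stips)
      got <- mine$per_species$status[mine$per_species$species == s]
      expect_equal(got == "monophyletic-with-support", oracle)
    }
  }
})

test_that("clean simulated data is fully discriminated except twins", {
  res <- small_sim(123, n_species = 10, ind = c(2, 3), twin_pairs = 1,
                   intra = 0.002, inter = 0.12)
  aln <- res$dataset$loci$L1
  tr <- bootstrap_support(aln, B = 100, seed = 5)
  rep <- species_discrimination(tr, res$dataset$samples, threshold = 0)
  twins <- unlist(res$truth$twins)
  failed <- rep$per_species$species[
    rep$per_species$status == "non-monophyletic"]
  expect_setequal(failed, twins)
})
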