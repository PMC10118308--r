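# Coupling-score ingestion, the Yeo-Johnson transform, and the three
# Z statistics.

test_that("read_coupling_scores mirrors pairs and rejects conflicts", {
  df <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), cn = c(0.5, 0.1, 0.2))
  cm <- read_coupling_scores(df, L = 3, neff = 6)
  expect_equal(cm$scores[1, 2], 0.5)
  expect_equal(cm$scores[2, 1], 0.5)
  expect_equal(cm$scores[3, 2], 0.2)
  expect_true(is.na(cm$scores[1, 1]))

  dup <- rbind(df, data.frame(i = 2, j = 1, cn = 0.5))
  expect_silent(cm2 <- read_coupling_scores(dup, L = 3))
  expect_equal(cm2$scores[1, 2], 0.5)

  conflict <- rbind(df, data.frame(i = 2, j = 1, cn = 0.6))
  expect_error(read_coupling_scores(conflict, L = 3), "conflict")
})

test_that("neff_filter uses the Neff/L >= 1 rule with inclusive boundary", {
  expect_true(neff_filter(cm_from_matrix(matrix(NA, 250, 250), neff = 500)))
  expect_false(neff_filter(cm_from_matrix(matrix(NA, 250, 250), neff = 100)))
  expect_true(neff_filter(cm_from_matrix(matrix(NA, 250, 250), neff = 250)))
})

test_that("yeo_johnson implements the four branches and is monotone", {
  expect_equal(yeo_johnson(0, -3), 0)
  expect_equal(yeo_johnson(0, 0), 0)
  expect_equal(yeo_johnson(0, 2), 0)
  x <- c(-4.3, -1, 0, 0.5, 2, 10)
  expect_equal(yeo_johnson(x, 1), x)              # identity at lambda 1
  expect_equal(yeo_johnson(exp(1) - 1, 0), 1)     # ln(e) = 1
  expect_equal(yeo_johnson(-1, 2), -log(2))       # negative branch, lambda 2
  expect_equal(yeo_johnson(-2, 0.5), -((3^1.5) - 1) / 1.5)
  for (lam in c(-2, 0, 0.7, 2, 3.5)) {
    y <- yeo_johnson(sort(x), lam)
    expect_true(all(diff(y) > 0))
  }
})

test_that("select_lambda maximises profile likelihood (scipy-verified)", {
  # frozen oracle values from scipy.stats.yeojohnson_normmax on the same
  # fixed samples
  set.seed(11); x <- rlnorm(200, -1, 0.7) - 0.2
  expect_equal(select_lambda(x), -2.0324980, tolerance = 1e-4)
  set.seed(12); y <- rnorm(150, 2, 1)
  expect_equal(select_lambda(y), 0.7953158, tolerance = 1e-4)

  set.seed(5)
  expect_equal(select_lambda(rnorm(5000)), 1, tolerance = 0.2)
  # log recovers normality when the sample is predominantly positive
  set.seed(6)
  expect_equal(select_lambda(exp(rnorm(5000, 2, 0.5)) - 1), 0,
               tolerance = 0.2)
  expect_error(select_lambda(c(1, 2, 3)), "at least 8")
  expect_error(select_lambda(rep(1, 20)), "constant")
})

test_that("interface_z matches hand arithmetic and the sign convention", {
  # focus pairs score {2, 3}; reference pairs {0, 1, 2}
  m <- matrix(NA_real_, 6, 6)
  m[1, 2] <- m[2, 1] <- 2; m[1, 3] <- m[3, 1] <- 3
  m[4, 5] <- m[5, 4] <- 0; m[4, 6] <- m[6, 4] <- 1; m[5, 6] <- m[6, 5] <- 2
  cm <- cm_from_matrix(m)
  z <- interface_z(cm, rbind(c(1, 2), c(1, 3)),
                   rbind(c(4, 5), c(4, 6), c(5, 6)), transform = FALSE)
  expect_equal(z$z, 1.5)           # (2.5 - 1) / sd({0,1,2}) = 1.5 / 1
  expect_equal(z$sd_reference, 1)

  # planted elevated cross-interface couplings give z > 0
  tr <- cached_dimer("SBS")$truth
  cp <- generate_couplings(tr, signal_spec(seed = 101))
  expect_gt(interface_z(cp$cm, tr$cross_pairs, tr$ref_pairs)$z, 0)
})

test_that("interface_z invariances: affine rescaling and lambda = 1", {
  tr <- cached_dimer("SBS")$truth
  cp <- generate_couplings(tr, signal_spec(seed = 7))
  z0 <- interface_z(cp$cm, tr$cross_pairs, tr$ref_pairs, transform = FALSE)
  cm2 <- cm_from_matrix(3 * cp$cm$scores + 2)
  z1 <- interface_z(cm2, tr$cross_pairs, tr$ref_pairs, transform = FALSE)
  expect_equal(z1$z, z0$z, tolerance = 1e-12)
  expect_equal(z1$p_value, z0$p_value, tolerance = 1e-12)

  # Yeo-Johnson at lambda = 1 equals the untransformed statistic
  zf <- .z_score_lambda1 <- quatfun:::.z_score(
    quatfun:::.pair_scores(cp$cm, tr$cross_pairs),
    quatfun:::.pair_scores(cp$cm, tr$ref_pairs),
    transform = TRUE, lambda = 1)
  expect_equal(zf$z, z0$z, tolerance = 1e-12)
})

test_that("Z statistics are invariant to coupling CSV row order", {
  tr <- cached_dimer("SBS")$truth
  cp <- generate_couplings(tr, signal_spec(seed = 8))
  tab <- cp$table
  set.seed(1)
  tab2 <- tab[sample.int(nrow(tab)), ]
  cm1 <- read_coupling_scores(tab, L = tr$L, neff = cp$neff)
  cm2 <- read_coupling_scores(tab2, L = tr$L, neff = cp$neff)
  z1 <- ligand_interface_z(cm1, tr$lbr_pos_all, tr$interface_pos,
                           tr$surface_pos)
  z2 <- ligand_interface_z(cm2, tr$lbr_pos_all, tr$interface_pos,
                           tr$surface_pos)
  expect_equal(z1$z, z2$z)
  expect_equal(z1$p_value, z2$p_value)
})

test_that("ligand_interface_z matches hand arithmetic and planted effects", {
  # lbr {1}; interface {2,3}; surface {4,5,6}
  m <- matrix(NA_real_, 6, 6)
  m[1, 2] <- m[2, 1] <- 0.16; m[1, 3] <- m[3, 1] <- 0.16
  m[1, 4] <- m[4, 1] <- 0.08; m[1, 5] <- m[5, 1] <- 0.10
  m[1, 6] <- m[6, 1] <- 0.12
  z <- ligand_interface_z(cm_from_matrix(m), 1, c(2, 3), c(4, 5, 6))
  expect_equal(z$z, 3)             # (0.16 - 0.10) / 0.02
  expect_false(z$transform$applied)

  tr <- cached_dimer("SBS")$truth
  hits <- vapply(1:50, function(s) {
    cp <- generate_couplings(tr, signal_spec(seed = s))
    z <- ligand_interface_z(cp$cm, tr$lbr_pos_all, tr$interface_pos,
                            tr$surface_pos)
    z$z > 0 && z$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("lbr_coevolution_z needs two LBRs and finds planted signal", {
  tr <- cached_dimer("SBS")$truth
  cp <- generate_couplings(tr, signal_spec(seed = 9))
  expect_error(lbr_coevolution_z(cp$cm, tr$lbr_pos_all[1], tr$surface_pos),
               "at least 2")
  z <- lbr_coevolution_z(cp$cm, tr$lbr_pos_all, tr$surface_pos)
  expect_gt(z$z, 0)
  expect_lt(z$p_value, 0.05)
  z0 <- lbr_coevolution_z(generate_couplings(tr, null_signal(9))$cm,
                          tr$lbr_pos_all, tr$surface_pos)
  expect_lt(abs(z0$z), 2.5)
})

test_that("select_best_ligand picks the argmax with documented tie-breaks", {
  res <- data.frame(ligand_id = c("L1", "L2"), value = c(1.2, 2.4),
                    site_type = c("SBS", "SBS"))
  expect_equal(select_best_ligand(res, "SBS"), "L2")

  tie <- data.frame(ligand_id = c("LB", "LA"), value = c(2, 2),
                    site_type = c("SBS", "SBS"))
  expect_equal(select_best_ligand(tie, "SBS"), "LA")

  mixed <- data.frame(ligand_id = c("L1", "L2"), value = c(9, 1),
                      site_type = c("SBS", "MBS"))
  expect_equal(select_best_ligand(mixed, "MBS"), "L2")
  expect_error(select_best_ligand(mixed[0, ], "SBS"), "no candidate")
})

test_that("coupling_pair_classes maps contacts and supports both policies", {
  d <- cached_dimer("SBS")
  ann <- cached_annotation("SBS")
  cls <- coupling_pair_classes(ann)
  # planted classes recovered from the structure annotation
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  expect_setequal(key(cls$cross_pairs), key(d$truth$cross_pairs))
  expect_setequal(key(cls$reference_pairs), key(d$truth$ref_pairs))

  allp <- coupling_pair_classes(ann, reference_policy = "all_pairs")
  expect_gt(nrow(allp$reference_pairs), nrow(cls$reference_pairs))
})
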