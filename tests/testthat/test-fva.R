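# Metabolic model ingestion, the simplex-backed FVA, gene knockouts and
# the affected/blocked criteria.

test_that("read_model validates structure and parses GPR rules", {
  m <- generate_network(redundant = FALSE)
  expect_s3_class(m, "MetabolicModel")
  expect_equal(dim(m$S), c(2L, 3L))         # boundary metabolites excluded
  expect_setequal(m$genes, c("g_up", "g_conv", "g_sink"))

  bad <- list(id = "x",
              metabolites = list(list(id = "A", boundary = FALSE)),
              reactions = list(list(id = "r", lb = 5, ub = 1, gpr = "",
                                    metabolites = list(A = 1))))
  expect_error(read_model(bad), "lower bound exceeds")
  unk <- list(id = "x",
              metabolites = list(list(id = "A", boundary = FALSE)),
              reactions = list(list(id = "r", lb = 0, ub = 1, gpr = "",
                                    metabolites = list(B = 1))))
  expect_error(read_model(unk), "unknown metabolite")
})

test_that("read_model round-trips through JSON on disk", {
  m <- generate_network(TRUE)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    id = "toy", metabolites = lapply(m$metabolites, function(id) {
      list(id = id, boundary = unname(m$boundary[id]))
    }),
    reactions = lapply(m$reactions, function(r) {
      mets <- m$S[, r]
      mets <- as.list(mets[mets != 0])
      # add back boundary stoichiometry lost in S (not needed for FVA)
      list(id = r, lb = unname(m$lb[r]), ub = unname(m$ub[r]),
           gpr = unname(m$gpr[r]), metabolites = mets)
    })), path, auto_unbox = TRUE)
  m2 <- read_model(path)
  expect_equal(run_fva(m2), run_fva(m))
})

test_that("FVA matches inspection solutions on toy networks", {
  lin <- generate_network(redundant = FALSE)
  fr <- run_fva(lin)
  expect_equal(fr$min, rep(0, 3))
  expect_equal(fr$max, rep(10, 3))

  red <- run_fva(generate_network(redundant = TRUE))
  # each parallel branch can be fully bypassed
  expect_equal(fr <- red$min[red$reaction %in% c("R_conv", "R_conv_iso")],
               c(0, 0))
  expect_equal(red$max[red$reaction == "R_sink"], 10)

  # pinned reaction has range (0, 0)
  pinned <- generate_network(FALSE)
  pinned$lb["R_conv"] <- 0; pinned$ub["R_conv"] <- 0
  fp <- run_fva(pinned)
  expect_equal(fp$max[fp$reaction == "R_conv"], 0)
  expect_equal(fp$max[fp$reaction == "R_sink"], 0)  # chain is dead
})

test_that("FVA agrees with an external LP oracle on a branched model", {
  # frozen expected ranges computed with scipy.optimize.linprog (HiGHS):
  # up [0,10], c1 [0,6], c2 [0,7], leak [0,2], sink [0,8]
  mod <- read_model(list(
    id = "branched",
    metabolites = list(list(id = "X", boundary = TRUE),
                       list(id = "A", boundary = FALSE),
                       list(id = "B", boundary = FALSE),
                       list(id = "Y", boundary = TRUE)),
    reactions = list(
      list(id = "up", lb = 0, ub = 20, gpr = "",
           metabolites = list(X = -1, A = 1)),
      list(id = "c1", lb = 0, ub = 6, gpr = "",
           metabolites = list(A = -1, B = 1)),
      list(id = "c2", lb = 0, ub = 7, gpr = "",
           metabolites = list(A = -1, B = 1)),
      list(id = "leak", lb = 0, ub = 2, gpr = "",
           metabolites = list(A = -1)),
      list(id = "sink", lb = 0, ub = 8, gpr = "",
           metabolites = list(B = -1, Y = 1)))))
  fr <- run_fva(mod)
  expect_equal(fr$max, c(10, 6, 7, 2, 8), tolerance = 1e-7)
  expect_equal(fr$min, rep(0, 5), tolerance = 1e-7)
})

test_that("FVA ranges are permutation-invariant and well-ordered", {
  m <- generate_network(TRUE)
  fr <- run_fva(m)
  expect_true(all(fr$min <= fr$max + 1e-9))
  perm <- c(3L, 1L, 4L, 2L)
  m2 <- m
  m2$S <- m$S[, perm]; m2$lb <- m$lb[perm]; m2$ub <- m$ub[perm]
  m2$gpr <- m$gpr[perm]; m2$reactions <- m$reactions[perm]
  fr2 <- run_fva(m2)
  expect_equal(fr2[match(fr$reaction, fr2$reaction), c("min", "max")],
               fr[, c("min", "max")], ignore_attr = TRUE)
})

test_that("knockout evaluates GPR boolean rules", {
  m <- read_model(list(
    id = "gpr",
    metabolites = list(list(id = "A", boundary = FALSE)),
    reactions = list(
      list(id = "r1", lb = 0, ub = 5, gpr = "g1",
           metabolites = list(A = 1)),
      list(id = "r2", lb = 0, ub = 5, gpr = "g1 or g2",
           metabolites = list(A = -1)),
      list(id = "r3", lb = -5, ub = 5, gpr = "(g1 and g2) or g3",
           metabolites = list(A = -1)))))
  k1 <- knockout(m, "g1")
  expect_equal(unname(k1$ub["r1"]), 0)                 # sole gene closes
  expect_equal(unname(k1$ub["r2"]), 5)                 # isozyme keeps open
  expect_equal(unname(k1$ub["r3"]), 5)                 # g3 rescues the AND
  k3 <- knockout(m, c("g1", "g3"))    # combined knockout
  expect_equal(unname(k3$ub["r3"]), 0)                 # both paths dead
  expect_equal(attr(k1, "disabled_reactions"), "r1")
  expect_error(knockout(m, "nope"), "unknown gene")
})

test_that("knockout_effect applies the 50% and 1e-6 criteria", {
  wild <- data.frame(reaction = c("a", "b", "c"), min = c(0, 0, 0),
                     max = c(10, 10, 0))
  ko <- data.frame(reaction = c("a", "b", "c"), min = c(0, 0, 0),
                   max = c(4, 6, 0))
  eff <- knockout_effect(wild, ko)
  expect_equal(eff$affected, "a")              # 4 < 5
  expect_true(eff$any_affected)                # 6 >= 5 not affected; c blocked in wild
  expect_true("c" %in% eff$blocked)

  ko2 <- data.frame(reaction = c("a", "b", "c"), min = c(0, 0, 0),
                    max = c(1e-9, 6, 0))
  expect_true("a" %in% knockout_effect(wild, ko2)$blocked)

  # monotone: tightening 50% -> 90% never adds affected reactions
  e50 <- knockout_effect(wild, ko, affected_threshold = 0.5)
  e90 <- knockout_effect(wild, ko, affected_threshold = 0.9)
  expect_true(all(e90$affected %in% e50$affected))
  expect_error(knockout_effect(wild, ko[1:2, ]), "different reactions")
})

test_that("redundant vs non-redundant knockouts behave as designed", {
  red <- generate_network(redundant = TRUE)
  scr <- knockout_screen(red, genes = c("g_conv", "g_iso"))
  expect_false(any(scr$any_affected))          # isozyme buffers both

  lin <- generate_network(redundant = FALSE)
  wild <- run_fva(lin)
  kom <- knockout(lin, "g_conv")
  eff <- knockout_effect(wild, run_fva(kom),
                         disabled = attr(kom, "disabled_reactions"))
  expect_true(eff$any_affected)
  expect_true(all(c("R_up", "R_sink") %in% eff$affected))
  expect_true(all(c("R_up", "R_conv", "R_sink") %in% eff$blocked))
})
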