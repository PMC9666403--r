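# Structure reading, secondary-structure annotation, and compositions.

test_that("a generated structure survives a write/read round trip", {
  dir <- withr::local_tempdir()
  toy <- make_toy_lattice(toy_lattice_params(n_theta = 4, n_z = 3, seed = 5),
                          dir = dir)
  model <- read_structure(file.path(dir, "toy_structure.pdb"),
                          chain_roles = c(A = "alpha", B = "beta"),
                          ligand_sites = c(A = "N-site", B = "E-site"),
                          quiet = TRUE)
  expect_identical(nrow(model$residues), nrow(toy$model$residues))
  expect_identical(model$residues$aa, toy$model$residues$aa)
  got <- as.matrix(model$atoms[, c("x", "y", "z")])
  want <- as.matrix(toy$model$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(got - want)), 1e-3)
  expect_length(model$ligands, 2L)
  expect_setequal(vapply(model$ligands, `[[`, "", "site"),
                  c("N-site", "E-site"))
  # annotate from the emitted file and compare against the generator
  model <- attach_secondary_structure(model, file.path(dir, "toy_ss.tsv"),
                                      quiet = TRUE)
  expect_identical(model$residues$ss3, toy$model$residues$ss3)
})

test_that("a demanded chain that is absent is a hard error", {
  dir <- withr::local_tempdir()
  make_toy_lattice(toy_lattice_params(n_theta = 4, n_z = 3, seed = 5),
                   dir = dir)
  expect_error(
    read_structure(file.path(dir, "toy_structure.pdb"),
                   chain_roles = c(A = "alpha", C = "beta"), quiet = TRUE),
    "chain C absent")
  expect_error(read_structure(file.path(dir, "nope.pdb"), c(A = "alpha")),
               "does not exist")
})

test_that("unannotated residues default to loop; bad annotations error", {
  toy <- get_small_toy()
  model <- toy$model
  model$residues$ss3 <- NA_character_
  nA <- sum(model$residues$chain == "A")
  ann <- data.frame(chain = "A", resnum = 1:5,
                    ss3 = c(rep("helix", 4), "sheet"))
  ann <- rbind(ann, data.frame(chain = "B",
                               resnum = model$residues$resno[model$residues$chain == "B"],
                               ss3 = "loop"))
  expect_message(model2 <- attach_secondary_structure(model, ann),
                 "defaulted to loop")
  rA <- model2$residues[model2$residues$chain == "A", ]
  expect_identical(rA$ss3[rA$resno <= 4], rep("helix", 4))
  expect_identical(rA$ss3[rA$resno == 5], "sheet")
  expect_identical(rA$ss3[rA$resno > 5], rep("loop", nA - 5L))

  dup <- rbind(ann, data.frame(chain = "A", resnum = 1, ss3 = "sheet"))
  expect_error(attach_secondary_structure(model, dup, quiet = TRUE),
               "conflicting duplicate")
  ghost <- data.frame(chain = "A", resnum = 99999, ss3 = "helix")
  expect_error(attach_secondary_structure(model, ghost, quiet = TRUE),
               "non-existent residue")
})

test_that("dssp codes reduce to the three-class vocabulary", {
  expect_identical(dssp3(c("H", "G", "I", "E", "B", "T", "S", "-", "helix")),
                   c("helix", "helix", "helix", "sheet", "sheet",
                     "loop", "loop", "loop", "helix"))
})

test_that("composition arithmetic and degenerate cases", {
  toy <- get_small_toy()
  # label the first 4 alpha residues helix, next 1 sheet, rest loop, and
  # restrict to a 10-residue window via a labeller on chain A
  labeller <- function(res) {
    ifelse(res$resno <= 4, "helix", ifelse(res$resno == 5, "sheet", "loop"))
  }
  sub <- toy$model
  keepA <- sub$residues$chain == "A" & sub$residues$resno <= 10
  sub$residues <- sub$residues[keepA, , drop = FALSE]
  sub$atoms <- sub$atoms[sub$atoms$chain == "A" & sub$atoms$resno <= 10, ,
                         drop = FALSE]
  sub$chain_roles <- c(A = "alpha")
  sub$ligands <- list()
  comp <- composition(sub, labeller)
  expect_equal(comp$fraction[match(c("helix", "sheet", "loop"),
                                   comp$category)],
               c(0.4, 0.1, 0.5))
  # degenerate: all one category
  comp1 <- composition(sub, function(res) rep("helix", nrow(res)))
  expect_equal(comp1$fraction[comp1$category == "helix"], 1)
  # unlabeled residue is a hard error
  expect_error(composition(sub, function(res) {
    out <- labeller(res); out[1] <- NA; out
  }), "unlabeled residue")
})

test_that("composition is permutation-invariant and adds over chains", {
  toy <- get_small_toy()
  comp_all <- composition(toy$model, "ss")
  perm <- toy$model
  set.seed(42)
  perm$residues <- perm$residues[sample(nrow(perm$residues)), , drop = FALSE]
  comp_perm <- composition(perm, "ss")
  expect_equal(comp_all$count, comp_perm$count)
  compA <- composition(toy$model, "ss", chains = "A")
  compB <- composition(toy$model, "ss", chains = "B")
  expect_equal(compA$count + compB$count, comp_all$count)
  expect_equal(sum(comp_all$fraction), 1, tolerance = 1e-9)
})

test_that("the alpha-tubulin-like annotation matches its own file tallies", {
  path <- system.file("extdata", "tuba1a_like_ss.tsv", package = "tubvar")
  ann <- read.delim(path)
  tallies <- table(ann$ss3) / nrow(ann)   # independent line-count oracle
  expect_equal(unname(tallies[c("helix", "sheet", "loop")]),
               c(0.39, 0.12, 0.49), tolerance = 0.005,
               ignore_attr = TRUE)
  # and through the model path: toy chain sized 451 with this annotation
  gen <- make_ss_annotation(n = 451, seed = 1)
  expect_identical(gen$ss3, ann$ss3)
})
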