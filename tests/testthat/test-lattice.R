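# Lattice neighborhood, interfaces, surface orientation, domain assignment.

test_that("a self-mapping transform is rejected as a degenerate lattice", {
  toy <- get_small_toy()
  bad <- toy$lattice
  bad$longitudinal <- rigid_transform(diag(3), c(0, 0, 0))
  expect_error(build_neighborhood(toy$model, bad), "degenerate lattice")
})

test_that("a far translation yields zero longitudinal contacts", {
  toy <- get_small_toy()
  far <- toy$lattice
  far$longitudinal <- rigid_transform(diag(3), c(0, 0, 500))
  nb <- build_neighborhood(toy$model, far)
  expect_identical(nrow(interface_residues(nb, "longitudinal")), 0L)
})

test_that("interface residues match the planted contact sets", {
  toy <- get_toy(2)
  nb <- build_neighborhood(toy$model, toy$lattice)
  truth <- toy$truth
  for (which in c("longitudinal", "lateral", "intradimer")) {
    got <- interface_residues(nb, which)
    got_key <- paste(got$chain, got$resno)
    # planted sets are pre-precedence: a pocket or higher-precedence residue
    # may also be in contact, so compare against the planted label plus any
    # higher-precedence planted members found in contact
    planted <- truth[truth$domain == which, , drop = FALSE]
    planted_key <- paste(planted$chain, planted$resno)
    expect_true(all(planted_key %in% got_key),
                info = paste("missed planted", which))
    higher <- switch(which,
                     longitudinal = c("GTP binding"),
                     lateral = c("GTP binding", "longitudinal"),
                     intradimer = c("GTP binding", "longitudinal", "lateral"))
    allowed <- paste(truth$chain, truth$resno)[truth$domain %in%
                                                 c(which, higher)]
    expect_true(all(got_key %in% allowed),
                info = paste("spurious", which, "contacts"))
  }
  # below bond distance nothing is in contact
  expect_identical(nrow(interface_residues(nb, "lateral", cutoff = 0.1)), 0L)
  expect_error(interface_residues(nb, "sideways"))
})

test_that("contact sets are nested in the cutoff", {
  toy <- get_small_toy()
  nb <- build_neighborhood(toy$model, toy$lattice)
  for (which in c("longitudinal", "lateral", "intradimer")) {
    s4 <- interface_residues(nb, which, cutoff = 4.0)
    s5 <- interface_residues(nb, which, cutoff = 5.0)
    expect_true(all(paste(s4$chain, s4$resno) %in% paste(s5$chain, s5$resno)))
  }
})

test_that("surface orientation separates outer, luminal, and buried", {
  toy <- get_toy(3)
  expo <- relative_exposure(toy$model)
  orient <- surface_orientation(toy$model, exposure = expo)
  truth_key <- paste(toy$truth$chain, toy$truth$resno, sep = ":")
  planted <- stats::setNames(toy$truth$domain, truth_key)
  # planted outer-surface residues face out, luminal ones face in
  expect_true(all(orient[names(planted)[planted == "MAP binding"]] == "outer"))
  expect_true(all(orient[names(planted)[planted == "lumen"]] == "luminal"))
  # planted interior residues are buried
  expect_true(all(orient[names(planted)[planted == "other"]] == "neither"))
  # fully buried residue by fiat: exposure forced to 0
  expo0 <- expo; expo0[] <- 0
  expect_true(all(surface_orientation(toy$model, exposure = expo0) ==
                    "neither"))
})

test_that("a radial inversion about the chain median swaps outer and luminal", {
  toy <- get_small_toy()
  model <- toy$model
  orient <- surface_orientation(model)
  # move every residue to the mirrored radius r -> 2*median - r
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  key <- paste(model$atoms$chain, model$atoms$resno, sep = ":")
  cen_r <- tapply(sqrt(xyz[, 1]^2 + xyz[, 2]^2), key, mean)
  med <- tapply(cen_r, sub(":.*", "", names(cen_r)), median)
  r_at <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  shift <- 2 * (cen_r[key] - med[sub(":.*", "", key)])
  scale <- (r_at - shift) / r_at
  model$atoms$x <- xyz[, 1] * scale
  model$atoms$y <- xyz[, 2] * scale
  flipped <- surface_orientation(model)
  # judge the swap on residues well away from the median radius: the planted
  # outer and luminal shells sit a full grid spacing off the mid-wall
  planted <- stats::setNames(toy$truth$domain,
                             paste(toy$truth$chain, toy$truth$resno,
                                   sep = ":"))
  outer_shell <- names(planted)[planted == "MAP binding"]
  inner_shell <- names(planted)[planted == "lumen"]
  expect_true(all(orient[outer_shell] == "outer"))
  expect_true(all(flipped[outer_shell] == "luminal"))
  expect_true(all(orient[inner_shell] == "luminal"))
  expect_true(all(flipped[inner_shell] == "outer"))
})

test_that("GTP precedence beats a coincident interface membership", {
  # plant the pocket on the intradimer row of the mid shell so pocket
  # residues are both nucleotide-proximal and interface members
  p <- toy_lattice_params(seed = 9)
  pocket <- c(1L + 2L + p$n_theta * ((p$n_z - 1L) + p$n_z * 1L),
              1L + 3L + p$n_theta * ((p$n_z - 1L) + p$n_z * 1L))
  toy <- make_toy_lattice(toy_lattice_params(seed = 9, pocket = pocket))
  part <- assign_domains(toy$model, toy$lattice)
  pr <- part[part$chain == "A" & part$resno %in% pocket, , drop = FALSE]
  expect_true(all(pr$domain == "GTP binding"))
  # the audit trail still records the coincident interface rule
  expect_true(all(grepl("intradimer", pr$evidence)))
})

test_that("the partition is total and matches planted labels", {
  toy <- get_toy(2)
  part <- assign_domains(toy$model, toy$lattice)
  expect_identical(nrow(part), nrow(toy$model$residues))
  expect_identical(sum(attr(part, "counts")), nrow(part))
  expect_true(all(part$domain %in%
                    c("longitudinal", "lateral", "MAP binding", "GTP binding",
                      "lumen", "intradimer", "other")))
  cmp <- recovered_vs_planted(toy, part)
  expect_gte(mean(cmp$recovered == cmp$planted), 0.95)
  # buried residue with no interface or ligand falls through to other
  expect_true(any(part$domain == "other" & part$evidence == ""))
})

test_that("domain labels are invariant under a global rigid motion", {
  toy <- get_small_toy()
  part0 <- assign_domains(toy$model, toy$lattice)
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  scene <- transform_scene(toy, R, c(12, -7, 30))
  part1 <- assign_domains(scene$model, scene$lattice)
  expect_identical(part1$domain, part0$domain)
})

test_that("lattice specs survive a JSON round trip", {
  toy <- get_small_toy()
  path <- withr::local_tempfile(fileext = ".json")
  write_lattice_spec(toy$lattice, path)
  back <- read_lattice_spec(path)
  expect_equal(back$longitudinal$rotation, toy$lattice$longitudinal$rotation)
  expect_equal(back$longitudinal$translation,
               toy$lattice$longitudinal$translation)
  expect_equal(back$lateral_right$rotation, toy$lattice$lateral_right$rotation)
  expect_equal(back$contact_cutoff, toy$lattice$contact_cutoff)
  # improper rotations are rejected
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})
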