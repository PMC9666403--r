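# Shared toy-lattice fixtures, generated once per test run.

.toy_cache <- new.env(parent = emptyenv())

get_toy <- function(seed = 1, ...) {
  key <- paste0("toy_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- make_toy_lattice(toy_lattice_params(seed = seed, ...))
  }
  .toy_cache[[key]]
}

# small lattice for quick structural tests: 4x3 grid, 36 residues per chain
get_small_toy <- function(seed = 5) get_toy(seed, n_theta = 4, n_z = 3)

toy_alpha_labels <- function(toy) {
  stats::setNames(toy$truth$domain[toy$truth$chain == "A"],
                  toy$truth$resno[toy$truth$chain == "A"])
}

toy_truth_labels <- function(toy) {
  stats::setNames(toy$truth$domain,
                  paste(toy$truth$chain, toy$truth$resno, sep = ":"))
}

toy_domain_composition <- function(toy, chains = "A") {
  composition(toy$model, toy_truth_labels(toy), chains = chains)
}

recovered_vs_planted <- function(toy, part = NULL) {
  if (is.null(part)) part <- assign_domains(toy$model, toy$lattice)
  m <- match(paste(part$chain, part$resno),
             paste(toy$truth$chain, toy$truth$resno))
  data.frame(chain = part$chain, resno = part$resno,
             recovered = part$domain, planted = toy$truth$domain[m],
             stringsAsFactors = FALSE)
}

residue_centroids_for_test <- function(model) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  key <- paste(model$atoms$chain, model$atoms$resno, sep = ":")
  f <- factor(key, levels = unique(key))
  cen <- cbind(tapply(xyz[, 1], f, mean), tapply(xyz[, 2], f, mean),
               tapply(xyz[, 3], f, mean))
  rownames(cen) <- levels(f)
  cen
}

# apply one global rigid motion to a model and conjugate the lattice spec
transform_scene <- function(toy, rotation, translation) {
  G <- rigid_transform(rotation, translation)
  model <- toy$model
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new_xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
  model$atoms$x <- new_xyz[, 1]; model$atoms$y <- new_xyz[, 2]
  model$atoms$z <- new_xyz[, 3]
  model$ligands <- lapply(model$ligands, function(lg) {
    lx <- as.matrix(lg$atoms[, c("x", "y", "z")])
    nl <- sweep(lx %*% t(rotation), 2, translation, "+")
    lg$atoms$x <- nl[, 1]; lg$atoms$y <- nl[, 2]; lg$atoms$z <- nl[, 3]
    lg
  })
  conj <- function(tr) {
    R2 <- rotation %*% tr$rotation %*% t(rotation)
    t2 <- as.numeric(rotation %*% tr$translation) + translation -
      as.numeric(R2 %*% translation)
    rigid_transform(R2, t2)
  }
  sp <- toy$lattice
  lattice <- lattice_spec(
    axis_point = as.numeric(rotation %*% sp$axis_point) + translation,
    axis_dir = as.numeric(rotation %*% sp$axis_dir),
    longitudinal = conj(sp$longitudinal),
    lateral_left = conj(sp$lateral_left),
    lateral_right = conj(sp$lateral_right),
    contact_cutoff = sp$contact_cutoff, ligand_cutoff = sp$ligand_cutoff)
  list(model = model, lattice = lattice)
}
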