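# Synthetic inputs: toy cylindrical lattices with planted domain ground
# truth, secondary-structure annotations with chosen class proportions, and
# variant tables with planted phenotype-by-category enrichment.

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

with_seed <- function(seed, code) {
  # force the seed before snapshotting the RNG state: a lazily evaluated
  # seed expression may itself consume random numbers
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Parameters of the toy cylindrical lattice
#'
#' The toy assembly emulates the microtubule wall at desk scale: each
#' pseudo-monomer is a grid of `n_theta x n_z` residues replicated on three
#' radial shells (luminal, mid-wall, outer), two monomers stack into a
#' pseudo-dimer, and rigid motions place the stacked and side neighbors. Each
#' pseudo-residue is a 5-atom stick motif (a centroid plus four tetrahedral
#' offsets) -- enough geometry for contacts, burial, and radial orientation.
#'
#' @param n_theta,n_z grid size of a monomer (columns around the cylinder,
#'   rows along the axis). `subunit_size = 3 * n_theta * n_z`.
#' @param radius mid-wall radius of the cylinder, Angstrom.
#' @param spacing grid spacing (and shell separation), Angstrom.
#' @param gap inter-subunit gap, Angstrom; must admit contacts below the
#'   default 4.5 cutoff without clashes.
#' @param jitter coordinate noise sd, Angstrom.
#' @param rise longitudinal offset of the next dimer; default the dimer
#'   height plus one gap.
#' @param twist lateral rotation to the neighboring protofilament, degrees;
#'   default the monomer's angular width plus one gap of arc.
#' @param pocket optional list with residue indices per chain for the planted
#'   nucleotide pocket; default a 2x2 mid-wall patch.
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @export
toy_lattice_params <- function(n_theta = 6, n_z = 5, radius = 60,
                               spacing = 6, gap = 4.5, jitter = 0.1,
                               rise = NULL, twist = NULL, pocket = NULL,
                               seed = 1) {
  if (radius <= 0 || spacing <= 0 || gap <= 0) {
    stop("radius, spacing, gap must be > 0")
  }
  if (n_theta < 3 || n_z < 3) stop("need at least a 3x3 monomer grid")
  if (gap < 3 || spacing < 3) {
    stop("geometrically impossible: subunits would clash (gap/spacing < 3 A)")
  }
  monomer_height <- (n_z - 1) * spacing
  dimer_height <- 2 * monomer_height + gap
  if (is.null(rise)) rise <- dimer_height + gap
  if (rise < dimer_height + 2) {
    stop("geometrically impossible: rise smaller than the dimer height")
  }
  width_arc <- (n_theta - 1) * spacing
  if (is.null(twist)) twist <- (width_arc + gap) / radius * 180 / pi
  if (twist * pi / 180 * radius < width_arc + 2) {
    stop("geometrically impossible: twist overlaps the neighboring subunit")
  }
  structure(list(n_theta = n_theta, n_z = n_z,
                 subunit_size = 3L * n_theta * n_z,
                 radius = radius, spacing = spacing, gap = gap,
                 jitter = jitter, rise = rise, twist = twist,
                 pocket = pocket, seed = as.integer(seed)),
            class = "toy_lattice_params")
}

# residue number from 0-based (layer, row, col)
toy_resno <- function(p, l, k, j) 1L + j + p$n_theta * (k + p$n_z * l)

toy_grid <- function(p) {
  g <- expand.grid(j = 0:(p$n_theta - 1), k = 0:(p$n_z - 1), l = 0:2)
  g$resno <- toy_resno(p, g$l, g$k, g$j)
  g[order(g$resno), , drop = FALSE]
}

default_pocket <- function(p) {
  kk <- unique(pmin(pmax(1L, floor(p$n_z / 2) + 0:1), p$n_z - 2L))
  jj <- unique(pmin(pmax(1L, floor(p$n_theta / 2) + 0:1), p$n_theta - 2L))
  cells <- expand.grid(j = jj, k = kk)
  sort(toy_resno(p, 1L, cells$k, cells$j))
}

planted_label <- function(p, g, pocket) {
  lab <- rep("other", nrow(g))
  lab[g$l == 2] <- "MAP binding"
  lab[g$l == 0] <- "lumen"
  lab[g$intradimer_row] <- "intradimer"
  lab[g$j == 0 | g$j == p$n_theta - 1] <- "lateral"
  lab[g$longitudinal_row] <- "longitudinal"
  lab[g$resno %in% pocket] <- "GTP binding"
  lab
}

TETRA <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

#' Generate a toy lattice with planted domain ground truth
#'
#' Builds the central pseudo-dimer (chains A = alpha, B = beta) with one
#' planted nucleotide per chain (N-site on A, E-site on B), the lattice
#' specification that regenerates its neighbors, a planted domain label for
#' every residue, and a secondary-structure annotation. Deterministic given
#' the seed. When `dir` is given, the structure (PDB), ground-truth labels
#' (TSV), secondary structure (TSV) and lattice (JSON) are written there.
#'
#' @param params a [toy_lattice_params()].
#' @param dir optional output directory.
#' @return List with `model` (a `structure_model` with ss3 attached), `truth`
#'   (data frame chain/resno/aa/ss3/domain), `lattice` (a `lattice_spec`),
#'   `params`, and `files` (paths, when written).
#' @export
make_toy_lattice <- function(params = toy_lattice_params(), dir = NULL) {
  stopifnot(inherits(params, "toy_lattice_params"))
  p <- params
  pocket <- if (is.null(p$pocket)) default_pocket(p) else sort(unique(p$pocket))
  if (any(pocket < 1 | pocket > p$subunit_size)) {
    stop("pocket indices outside the subunit range")
  }
  g <- toy_grid(p)
  monomer_height <- (p$n_z - 1) * p$spacing

  with_seed(p$seed, {
    chains <- c(A = "alpha", B = "beta")
    all_res <- list(); all_atoms <- list(); ligands <- list()
    for (ci in seq_along(chains)) {
      ch <- names(chains)[ci]
      z0 <- (ci - 1) * (monomer_height + p$gap)
      theta <- g$j * p$spacing / p$radius
      r <- p$radius + (g$l - 1) * p$spacing
      cen <- cbind(r * cos(theta), r * sin(theta), z0 + g$k * p$spacing)
      gg <- g
      gg$longitudinal_row <- if (chains[[ci]] == "alpha") gg$k == 0 else
        gg$k == p$n_z - 1
      gg$intradimer_row <- if (chains[[ci]] == "alpha") gg$k == p$n_z - 1 else
        gg$k == 0
      lab <- planted_label(p, gg, pocket)
      aa <- sample(AA_ONE, nrow(g), replace = TRUE)
      all_res[[ch]] <- data.frame(chain = ch, resno = g$resno, aa = aa,
                                  domain = lab, stringsAsFactors = FALSE)
      # 5-atom stick motif per residue
      nres <- nrow(g)
      offs <- rbind(c(0, 0, 0), TETRA * 1.2)
      anames <- c("CA", "N", "C", "O", "CB")
      axyz <- cen[rep(seq_len(nres), each = 5L), , drop = FALSE] +
        offs[rep(1:5, nres), , drop = FALSE]
      axyz <- axyz + matrix(stats::rnorm(length(axyz), sd = p$jitter),
                            ncol = 3)
      all_atoms[[ch]] <- data.frame(
        chain = ch, resno = rep(g$resno, each = 5L),
        elety = rep(anames, nres),
        x = axyz[, 1], y = axyz[, 2], z = axyz[, 3],
        stringsAsFactors = FALSE)
      # planted nucleotide: one ligand atom 2 A from each pocket residue,
      # pulled toward the pocket centroid
      pk <- match(pocket, g$resno)
      pc <- colMeans(cen[pk, , drop = FALSE])
      lxyz <- t(vapply(pk, function(i) {
        v <- pc - cen[i, ]
        nv <- sqrt(sum(v^2))
        if (nv < 1e-9) cen[i, ] + c(0, 0, 2) else cen[i, ] + 2 * v / nv
      }, numeric(3)))
      ligands[[ch]] <- list(
        name = "GTP", chain = ch,
        site = if (chains[[ci]] == "alpha") "N-site" else "E-site",
        atoms = data.frame(
          elety = paste0("P", seq_len(nrow(lxyz))),
          x = lxyz[, 1], y = lxyz[, 2], z = lxyz[, 3],
          stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, all_res)
    atoms <- do.call(rbind, all_atoms)
    rownames(res) <- rownames(atoms) <- NULL

    ss <- do.call(rbind, lapply(names(chains), function(ch) {
      make_ss_annotation(n = p$subunit_size, chain = ch,
                         seed = p$seed + match(ch, names(chains)))
    }))
    residues <- data.frame(chain = res$chain, resno = res$resno, aa = res$aa,
                           ss3 = ss$ss3[match(paste(res$chain, res$resno),
                                              paste(ss$chain, ss$resnum))],
                           stringsAsFactors = FALSE)
    model <- new_structure_model(atoms, residues, chains,
                                 unname(ligands))
    validate_structure_model(model)

    lattice <- lattice_spec(
      axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
      longitudinal = rigid_transform(diag(3), c(0, 0, p$rise)),
      lateral_left = rigid_transform(rotation_about_z(-p$twist * pi / 180),
                                     c(0, 0, 0)),
      lateral_right = rigid_transform(rotation_about_z(p$twist * pi / 180),
                                      c(0, 0, 0)))

    truth <- data.frame(chain = res$chain, resno = res$resno, aa = res$aa,
                        ss3 = residues$ss3, domain = res$domain,
                        stringsAsFactors = FALSE)
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(structure = file.path(dir, "toy_structure.pdb"),
                    truth = file.path(dir, "toy_truth.tsv"),
                    ss = file.path(dir, "toy_ss.tsv"),
                    lattice = file.path(dir, "toy_lattice.json"))
      write_toy_pdb(model, files$structure)
      utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(
        data.frame(chain = truth$chain, resnum = truth$resno,
                   ss3 = truth$ss3),
        files$ss, sep = "\t", quote = FALSE, row.names = FALSE)
      write_lattice_spec(lattice, files$lattice)
    }
    list(model = model, truth = truth, lattice = lattice, params = p,
         pocket = pocket, files = files)
  })
}

# Minimal fixed-format PDB writer for the toy generator. The reader side is
# bio3d, so write->read round-trips cross two implementations.
write_toy_pdb <- function(model, path) {
  fmt <- function(record, serial, name, resn, chain, resno, x, y, z, elem) {
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, nm, "", resn, chain, resno, "", x, y, z,
            1.00, 0.00, elem)
  }
  lines <- character(0)
  serial <- 0L
  at <- model$atoms
  res <- model$residues
  aa3 <- stats::setNames(AA_ONE_TO_THREE[res$aa], paste(res$chain, res$resno))
  for (i in seq_len(nrow(at))) {
    serial <- serial + 1L
    lines[length(lines) + 1L] <- fmt(
      "ATOM", serial, at$elety[i], aa3[[paste(at$chain[i], at$resno[i])]],
      at$chain[i], at$resno[i], at$x[i], at$y[i], at$z[i],
      substr(at$elety[i], 1, 1))
  }
  for (lg in model$ligands) {
    for (i in seq_len(nrow(lg$atoms))) {
      serial <- serial + 1L
      lines[length(lines) + 1L] <- fmt(
        "HETATM", serial, lg$atoms$elety[i], lg$name, lg$chain, 501L,
        lg$atoms$x[i], lg$atoms$y[i], lg$atoms$z[i],
        substr(lg$atoms$elety[i], 1, 1))
    }
  }
  lines[length(lines) + 1L] <- "END"
  writeLines(lines, path)
  invisible(path)
}

#' Secondary-structure annotation with chosen class proportions
#'
#' Allocates helix/sheet/loop labels to `n` residues so the class counts
#' match the requested proportions as closely as integers allow (largest
#' remainder rule), then scatters them over positions. Useful both for toy
#' chains and for emulating an alpha-tubulin-like composition (about 39%
#' helix, 12% sheet, 49% loop over 451 residues).
#'
#' @param n number of residues.
#' @param props named proportions over helix/sheet/loop, summing to 1.
#' @param chain chain id for the output rows.
#' @param seed RNG seed for the positional scatter.
#' @param path optional TSV output path (columns chain, resnum, ss3).
#' @return Data frame with columns `chain`, `resnum`, `ss3`.
#' @export
make_ss_annotation <- function(n = 451,
                               props = c(helix = 0.39, sheet = 0.12,
                                         loop = 0.49),
                               chain = "A", seed = 1, path = NULL) {
  if (!setequal(names(props), SS_LEVELS)) {
    stop("props must be named helix, sheet, loop")
  }
  props <- props[SS_LEVELS]
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(props * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  labels <- rep(SS_LEVELS, base)
  labels <- with_seed(seed, sample(labels))
  out <- data.frame(chain = chain, resnum = seq_len(n), ss3 = labels,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Variant table with planted phenotype-by-category enrichment
#'
#' Draws missense variants position-wise: within the target phenotype,
#' positions in the target category carry relative weight `fold`, all other
#' positions weight 1 (fold = 1 is the composition-proportional null). The
#' mutant residue is uniform over the 19 alternatives to the wild type.
#' Deterministic given the seed.
#'
#' @param labels named character vector, residue position to category.
#' @param wt_of named character vector, residue position to wild-type amino
#'   acid.
#' @param n_per_phenotype named counts per phenotype label (may include
#'   `not_available`). Default: 30 variants in each of the four clinical
#'   phenotypes.
#' @param target_phenotype,target_category the planted cell (both `NULL` for
#'   the null).
#' @param fold relative sampling weight `>= 1` for the planted cell.
#' @param seed RNG seed.
#' @param classify compute the property-change flags per row (disable inside
#'   tight simulation loops).
#' @param path optional TSV output path (columns substitution, phenotype).
#' @return A `mutation_table`.
#' @export
make_variant_table <- function(labels, wt_of,
                               n_per_phenotype = c(lissencephaly = 30,
                                                   microlissencephaly = 30,
                                                   pachygyria = 30,
                                                   polymicrogyria = 30),
                               target_phenotype = NULL,
                               target_category = NULL,
                               fold = 1, seed = 1, classify = TRUE,
                               path = NULL) {
  if (length(labels) == 0L) stop("empty label map")
  if (fold < 1) stop("fold must be >= 1")
  if (any(n_per_phenotype < 0)) stop("counts must be >= 0")
  bad <- setdiff(names(n_per_phenotype), PHENOTYPE_LEVELS)
  if (length(bad)) stop(sprintf("unknown phenotype(s): %s",
                                paste(bad, collapse = ", ")))
  positions <- as.integer(names(labels))
  if (anyNA(positions)) stop("labels must be named by residue position")
  if (!all(as.character(positions) %in% names(wt_of))) {
    stop("wt_of must cover every labeled position")
  }
  props <- property_table()
  rows <- with_seed(seed, {
    out <- list()
    for (m in names(n_per_phenotype)) {
      nm <- n_per_phenotype[[m]]
      if (nm == 0) next
      w <- rep(1, length(positions))
      if (!is.null(target_phenotype) && identical(m, target_phenotype) &&
          !is.null(target_category)) {
        w[unname(labels) == target_category] <- fold
      }
      pos <- sample(positions, nm, replace = TRUE, prob = w)
      wt <- unname(wt_of[as.character(pos)])
      mut <- vapply(wt, function(a) sample(setdiff(AA_ONE, a), 1L),
                    character(1))
      out[[m]] <- data.frame(substitution = paste0(wt, pos, mut),
                             wt_aa = wt, position = pos, mut_aa = mut,
                             phenotype = m, stringsAsFactors = FALSE)
    }
    out
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(substitution = character(0), wt_aa = character(0),
               position = integer(0), mut_aa = character(0),
               phenotype = character(0), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (classify && nrow(df)) {
    flags <- t(vapply(seq_len(nrow(df)), function(i) {
      fl <- classify_substitution(df$wt_aa[i], df$mut_aa[i], props)
      c(charge_loss_or_swap = "charge_loss_or_swap" %in% fl,
        charge_gain = "charge_gain" %in% fl,
        hydrophobicity_change = "hydrophobicity_change" %in% fl,
        no_change = "no_change" %in% fl)
    }, logical(4)))
    df <- cbind(df, as.data.frame(flags))
  }
  if (!is.null(path)) {
    utils::write.table(df[, c("substitution", "phenotype"), drop = FALSE],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  new_mutation_table(df, props)
}

#' Alpha-chain sequence map of a model
#'
#' @param model a `structure_model`.
#' @return Named character vector, residue number to amino acid, over the
#'   chains with role `alpha`.
#' @export
alpha_sequence <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  ch <- names(model$chain_roles)[model$chain_roles == "alpha"]
  res <- model$residues[model$residues$chain %in% ch, , drop = FALSE]
  stats::setNames(res$aa, res$resno)
}

#' Calibration / power simulation for the enrichment scan
#'
#' Repeatedly draws variant tables (null when `fold = 1`, planted enrichment
#' otherwise), runs the enrichment scan, and reports the per-cell rejection
#' frequency at `alpha`, plus -- when a target cell is planted -- how often
#' that cell attains the scan's minimum p-value.
#'
#' @param labels,wt_of,n_per_phenotype,target_phenotype,target_category,fold
#'   passed to [make_variant_table()].
#' @param composition the residue `composition_table` for the scanned
#'   category scheme.
#' @param replicates number of replicates, `>= 1`.
#' @param alpha rejection threshold.
#' @param background passed to [enrichment_scan()].
#' @param seed RNG seed (one stream drives all replicates).
#' @return A `simulation_summary`: data frame of cells with columns
#'   `phenotype`, `category`, `rejections`, `replicates`, `rejection_rate`,
#'   with attributes `min_p_rate` (frequency the planted cell attains the
#'   minimum p; `NA` under the null), `fold` and `alpha`.
#' @export
run_simulation_study <- function(labels, composition, wt_of,
                                 n_per_phenotype = c(lissencephaly = 30,
                                                     microlissencephaly = 30,
                                                     pachygyria = 30,
                                                     polymicrogyria = 30),
                                 target_phenotype = NULL,
                                 target_category = NULL, fold = 1,
                                 replicates = 100, alpha = 0.05,
                                 background = "residues", seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  planted <- !is.null(target_phenotype) && !is.null(target_category)
  cats <- composition$category
  rej <- matrix(0L, nrow = length(CLINICAL_PHENOTYPES), ncol = length(cats),
                dimnames = list(CLINICAL_PHENOTYPES, cats))
  min_hits <- 0L
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      rep_seed <- sample.int(.Machine$integer.max, 1L)
      tbl <- make_variant_table(labels, wt_of, n_per_phenotype,
                                target_phenotype, target_category, fold,
                                seed = rep_seed, classify = FALSE)
      scan <- suppressWarnings(
        enrichment_scan(tbl, labels, composition, background = background,
                        alpha = alpha))
      pm <- matrix(scan$results$p, ncol = length(CLINICAL_PHENOTYPES),
                   dimnames = list(cats, CLINICAL_PHENOTYPES))
      rej <- rej + t(pm < alpha)
      if (planted) {
        pt <- pm[target_category, target_phenotype]
        if (pt <= min(pm) + 1e-15) min_hits <- min_hits + 1L
      }
    }
  })
  out <- data.frame(phenotype = rep(CLINICAL_PHENOTYPES, times = length(cats)),
                    category = rep(cats, each = length(CLINICAL_PHENOTYPES)),
                    rejections = as.integer(rej),
                    replicates = replicates,
                    stringsAsFactors = FALSE)
  out$rejection_rate <- out$rejections / replicates
  structure(out,
            min_p_rate = if (planted) min_hits / replicates else NA_real_,
            fold = fold, alpha = alpha,
            target = if (planted) c(target_phenotype, target_category) else NULL,
            class = c("simulation_summary", "data.frame"))
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("Simulation study: %d replicates, fold = %g, alpha = %g\n",
              x$replicates[1], attr(x, "fold"), attr(x, "alpha")))
  if (!is.na(attr(x, "min_p_rate"))) {
    tg <- attr(x, "target")
    cat(sprintf("  planted cell %s / %s attains min p in %.1f%% of replicates\n",
                tg[1], tg[2], 100 * attr(x, "min_p_rate")))
  }
  print.data.frame(x)
  invisible(x)
}
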