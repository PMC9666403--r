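# Microtubule lattice neighborhood model and the seven-domain partition.

DOMAIN_LEVELS <- c("longitudinal", "lateral", "MAP binding", "GTP binding",
                   "lumen", "intradimer", "other")

#' Rigid transform
#'
#' A proper rigid motion: `x' = R x + t`, validated to be orthonormal with
#' determinant +1.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (Angstrom).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

apply_transform <- function(xyz, tr) {
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

invert_transform <- function(tr) {
  rigid_transform(t(tr$rotation),
                  as.numeric(-t(tr$rotation) %*% tr$translation))
}

#' Lattice specification for the microtubule neighborhood
#'
#' Describes how to place the neighbors of the central heterodimer in the
#' microtubule lattice: the long axis of the cylinder, the rigid motion to the
#' next dimer along the protofilament, the two rigid motions to the left and
#' right protofilament neighbors, and the distance cutoffs for interface and
#' ligand contacts.
#'
#' @param axis_point a point on the microtubule axis.
#' @param axis_dir unit direction of the axis.
#' @param longitudinal [rigid_transform()] placing the next dimer up the
#'   protofilament (its inverse places the one below).
#' @param lateral_left,lateral_right [rigid_transform()]s placing the two
#'   lateral protofilament neighbors.
#' @param contact_cutoff heavy-atom interface cutoff in Angstrom (default 4.5).
#' @param ligand_cutoff heavy-atom nucleotide-pocket cutoff in Angstrom
#'   (default 4.0).
#' @export
lattice_spec <- function(axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                         longitudinal, lateral_left, lateral_right,
                         contact_cutoff = 4.5, ligand_cutoff = 4.0) {
  axis_dir <- as.numeric(axis_dir)
  nrm <- sqrt(sum(axis_dir^2))
  if (nrm < 1e-12) stop("axis direction must be non-zero")
  axis_dir <- axis_dir / nrm
  if (contact_cutoff <= 0 || ligand_cutoff <= 0) stop("cutoffs must be > 0")
  for (tr in list(longitudinal, lateral_left, lateral_right)) {
    if (!inherits(tr, "rigid_transform")) {
      stop("transforms must be rigid_transform objects")
    }
  }
  structure(list(axis_point = as.numeric(axis_point), axis_dir = axis_dir,
                 longitudinal = longitudinal, lateral_left = lateral_left,
                 lateral_right = lateral_right,
                 contact_cutoff = contact_cutoff,
                 ligand_cutoff = ligand_cutoff),
            class = "lattice_spec")
}

#' Write / read a lattice specification as JSON
#'
#' Rotations are stored as 3x3 matrix rows, translations and the axis as
#' plain vectors, cutoffs in Angstrom.
#'
#' @param spec a [lattice_spec()].
#' @param path JSON file path.
#' @export
write_lattice_spec <- function(spec, path) {
  stopifnot(inherits(spec, "lattice_spec"))
  tr_json <- function(tr) {
    list(rotation = apply(tr$rotation, 1, function(r) as.numeric(r),
                          simplify = FALSE),
         translation = as.numeric(tr$translation))
  }
  obj <- list(axis = list(point = spec$axis_point, direction = spec$axis_dir),
              longitudinal = tr_json(spec$longitudinal),
              lateral_left = tr_json(spec$lateral_left),
              lateral_right = tr_json(spec$lateral_right),
              contact_cutoff = spec$contact_cutoff,
              ligand_cutoff = spec$ligand_cutoff)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_lattice_spec
#' @export
read_lattice_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("lattice file '%s' does not exist", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # rotation was serialized as a list of rows
  mk <- function(x) rigid_transform(matrix(as.numeric(t(x$rotation)), 3, 3,
                                           byrow = TRUE), x$translation)
  lattice_spec(axis_point = obj$axis$point, axis_dir = obj$axis$direction,
               longitudinal = mk(obj$longitudinal),
               lateral_left = mk(obj$lateral_left),
               lateral_right = mk(obj$lateral_right),
               contact_cutoff = obj$contact_cutoff,
               ligand_cutoff = obj$ligand_cutoff)
}

model_xyz <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# For each row of A, the minimum Euclidean distance to any row of B.
# Chunked so the dense distance block stays small.
min_dist_to <- function(A, B, chunk = 2000L) {
  nA <- nrow(A)
  out <- rep(Inf, nA)
  if (nA == 0L || nrow(B) == 0L) return(out)
  b2 <- rowSums(B^2)
  for (s in seq(1L, nA, by = chunk)) {
    e <- min(s + chunk - 1L, nA)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), b2, "+") - 2 * Ab %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Build the five-dimer lattice neighborhood
#'
#' Expands the central heterodimer into its microtubule neighborhood: one
#' longitudinal dimer above, one below (inverse transform), and the two
#' lateral protofilament neighbors. Central coordinates are unchanged. A
#' transform that maps the dimer onto itself (more than 10% of central atoms
#' within 1 Angstrom of a neighbor atom) is rejected as a degenerate lattice.
#'
#' @param model a `structure_model`.
#' @param lattice a [lattice_spec()].
#' @return A `lattice_neighborhood`: the central model plus neighbor atom
#'   coordinate matrices `long_up`, `long_down`, `lat_left`, `lat_right`.
#' @export
build_neighborhood <- function(model, lattice) {
  stopifnot(inherits(model, "structure_model"),
            inherits(lattice, "lattice_spec"))
  xyz <- model_xyz(model)
  nb <- list(
    long_up = apply_transform(xyz, lattice$longitudinal),
    long_down = apply_transform(xyz, invert_transform(lattice$longitudinal)),
    lat_left = apply_transform(xyz, lattice$lateral_left),
    lat_right = apply_transform(xyz, lattice$lateral_right))
  for (nm in names(nb)) {
    frac <- mean(min_dist_to(xyz, nb[[nm]]) < 1)
    if (frac > 0.10) {
      stop(sprintf("degenerate lattice: %s transform clashes with the central dimer (%.0f%% of atoms within 1 A)",
                   nm, 100 * frac))
    }
  }
  structure(list(central = model, neighbors = nb, lattice = lattice),
            class = "lattice_neighborhood")
}

residue_min_dist <- function(model, partner_xyz) {
  d <- min_dist_to(model_xyz(model), partner_xyz)
  key <- paste(model$atoms$chain, model$atoms$resno)
  as.numeric(tapply(d, factor(key, levels = unique(key)), min))
}

#' Interface residues of the central dimer
#'
#' Residues of the central dimer with at least one heavy atom within `cutoff`
#' of any heavy atom of the specified partner: the stacked dimers
#' (`longitudinal`), the side dimers (`lateral`), or the other chain of the
#' central dimer (`intradimer`).
#'
#' @param nbhd a `lattice_neighborhood` from [build_neighborhood()].
#' @param which one of `"longitudinal"`, `"lateral"`, `"intradimer"`.
#' @param cutoff Angstrom; defaults to the lattice `contact_cutoff`.
#' @return Data frame with columns `chain`, `resno`, `min_dist` for residues
#'   in contact.
#' @export
interface_residues <- function(nbhd,
                               which = c("longitudinal", "lateral",
                                         "intradimer"),
                               cutoff = NULL) {
  stopifnot(inherits(nbhd, "lattice_neighborhood"))
  which <- match.arg(which)
  if (is.null(cutoff)) cutoff <- nbhd$lattice$contact_cutoff
  if (cutoff <= 0) stop("cutoff must be > 0")
  model <- nbhd$central
  res <- model$residues
  if (which == "intradimer") {
    roles <- model$chain_roles
    d <- rep(Inf, nrow(res))
    for (ch in names(roles)) {
      partner_chains <- names(roles)[roles != roles[[ch]]]
      if (!length(partner_chains)) next
      sub <- model$atoms$chain == ch
      pxyz <- model_xyz(model)[model$atoms$chain %in% partner_chains, ,
                               drop = FALSE]
      dd <- min_dist_to(model_xyz(model)[sub, , drop = FALSE], pxyz)
      key <- paste(model$atoms$chain[sub], model$atoms$resno[sub])
      rmin <- tapply(dd, factor(key, levels = unique(key)), min)
      idx <- match(names(rmin), paste(res$chain, res$resno))
      d[idx] <- pmin(d[idx], as.numeric(rmin))
    }
  } else {
    partner <- if (which == "longitudinal") {
      rbind(nbhd$neighbors$long_up, nbhd$neighbors$long_down)
    } else {
      rbind(nbhd$neighbors$lat_left, nbhd$neighbors$lat_right)
    }
    d <- residue_min_dist(model, partner)
  }
  hit <- is.finite(d) & d <= cutoff
  out <- data.frame(chain = res$chain[hit], resno = res$resno[hit],
                    min_dist = d[hit], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Relative solvent exposure by neighbor counting
#'
#' Approximates burial by counting residue centroids within `radius` of each
#' residue centroid and rescaling: `exposure = 1 - n / max(n)`. Densely packed
#' residues score 0; the most isolated score toward 1. This is a
#' coordination-number approximation in the spirit of half-sphere exposure,
#' not a rolling-probe accessible surface area.
#'
#' @param model a `structure_model`.
#' @param radius neighbor-count radius in Angstrom (default 9.5).
#' @return Named numeric vector keyed `"chain:resno"`, values in `[0, 1]`.
#' @export
relative_exposure <- function(model, radius = 9.5) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- model_xyz(model)
  key <- paste(model$atoms$chain, model$atoms$resno, sep = ":")
  f <- factor(key, levels = unique(key))
  cen <- cbind(tapply(xyz[, 1], f, mean), tapply(xyz[, 2], f, mean),
               tapply(xyz[, 3], f, mean))
  d2 <- outer(rowSums(cen^2), rowSums(cen^2), "+") - 2 * cen %*% t(cen)
  n <- rowSums(d2 <= radius^2) - 1L
  mx <- max(n)
  expo <- if (mx == 0L) rep(1, length(n)) else 1 - n / mx
  stats::setNames(as.numeric(expo), levels(f))
}

residue_centroids <- function(model) {
  xyz <- model_xyz(model)
  key <- paste(model$atoms$chain, model$atoms$resno, sep = ":")
  f <- factor(key, levels = unique(key))
  cen <- cbind(tapply(xyz[, 1], f, mean), tapply(xyz[, 2], f, mean),
               tapply(xyz[, 3], f, mean))
  rownames(cen) <- levels(f)
  cen
}

radial_coordinate <- function(points, axis_point, axis_dir) {
  v <- sweep(points, 2, axis_point, "-")
  proj <- as.numeric(v %*% axis_dir)
  perp <- v - outer(proj, axis_dir)
  sqrt(rowSums(perp^2))
}

#' Outer / luminal surface orientation
#'
#' Classifies each residue by which wall of the microtubule cylinder it
#' faces. Exposed residues (relative exposure at or above the burial
#' threshold) are `outer` when their centroid's radial coordinate exceeds the
#' chain's median radial coordinate and `luminal` when below; buried residues
#' are `neither`. The outer surface is the MAP-binding face; the luminal side
#' faces the microtubule interior.
#'
#' @param model a `structure_model`.
#' @param axis_point,axis_dir the microtubule axis.
#' @param exposure named exposure vector from [relative_exposure()]
#'   (computed if `NULL`).
#' @param burial_threshold exposure below this is buried (default 0.15).
#' @param exposure_radius passed to [relative_exposure()] when computing.
#' @return Named character vector keyed `"chain:resno"` over
#'   `c("outer", "luminal", "neither")`.
#' @export
surface_orientation <- function(model, axis_point = c(0, 0, 0),
                                axis_dir = c(0, 0, 1), exposure = NULL,
                                burial_threshold = 0.15,
                                exposure_radius = 9.5) {
  stopifnot(inherits(model, "structure_model"))
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  if (is.null(exposure)) exposure <- relative_exposure(model, exposure_radius)
  cen <- residue_centroids(model)
  r <- radial_coordinate(cen, axis_point, axis_dir)
  names(r) <- rownames(cen)
  chain_of <- sub(":.*$", "", rownames(cen))
  med <- tapply(r, chain_of, stats::median)
  out <- rep("neither", length(r))
  exposed <- exposure[rownames(cen)] >= burial_threshold
  out[exposed & r > med[chain_of]] <- "outer"
  out[exposed & r <= med[chain_of]] <- "luminal"
  stats::setNames(out, rownames(cen))
}

#' Domain assignment rules
#'
#' Precedence order and burial criterion for the seven-domain partition. The
#' default order puts the GTP pocket first (a variant at a GTP-binding
#' residue is classified only as GTP binding), then the specific interfaces,
#' then the two surface classes, with `other` as the fall-through.
#'
#' @param precedence ordered labels; must be a permutation of the six
#'   non-`other` domains.
#' @param burial_threshold relative exposure below which a residue is buried
#'   (default 0.15).
#' @param exposure_method currently `"neighbor-count"`.
#' @param exposure_radius radius for the neighbor-count exposure (Angstrom).
#' @export
domain_rules <- function(precedence = c("GTP binding", "longitudinal",
                                        "lateral", "intradimer",
                                        "MAP binding", "lumen"),
                         burial_threshold = 0.15,
                         exposure_method = "neighbor-count",
                         exposure_radius = 9.5) {
  if (!setequal(precedence, setdiff(DOMAIN_LEVELS, "other")) ||
      length(precedence) != 6L) {
    stop("precedence must be a permutation of the six non-'other' domains")
  }
  if (burial_threshold < 0 || burial_threshold > 1) {
    stop("burial_threshold must be in [0, 1]")
  }
  exposure_method <- match.arg(exposure_method, "neighbor-count")
  structure(list(precedence = precedence,
                 burial_threshold = burial_threshold,
                 exposure_method = exposure_method,
                 exposure_radius = exposure_radius),
            class = "domain_rules")
}

ligand_pocket_distances <- function(model, sites = c("N-site", "E-site")) {
  ligs <- Filter(function(lg) lg$site %in% sites, model$ligands)
  res <- model$residues
  if (!length(ligs)) return(rep(Inf, nrow(res)))
  lxyz <- do.call(rbind, lapply(ligs, function(lg) {
    as.matrix(lg$atoms[, c("x", "y", "z")])
  }))
  residue_min_dist(model, lxyz)
}

#' Partition every residue into one functional domain
#'
#' Applies the lattice-neighborhood contact model, nucleotide proximity,
#' burial, and radial orientation to give each residue exactly one of the
#' seven functional domains, with first-match-wins precedence (GTP binding
#' before the interfaces before the surface classes). Every triggered rule is
#' recorded with its distance so alternative precedence orders are auditable.
#'
#' @param model a `structure_model`.
#' @param lattice a [lattice_spec()].
#' @param rules a [domain_rules()].
#' @return A `domain_partition`: data frame with columns `chain`, `resno`,
#'   `aa`, `ss3`, `domain`, `evidence`, plus attributes `counts` and `rules`.
#' @export
assign_domains <- function(model, lattice, rules = domain_rules()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(lattice, "lattice_spec"),
            inherits(rules, "domain_rules"))
  nbhd <- build_neighborhood(model, lattice)
  res <- model$residues
  rkey <- paste(res$chain, res$resno, sep = ":")
  n <- nrow(res)

  dist_of <- function(df) {
    d <- rep(NA_real_, n)
    m <- match(paste(df$chain, df$resno, sep = ":"), rkey)
    d[m] <- df$min_dist
    d
  }
  gtp_d <- ligand_pocket_distances(model)
  member <- list(
    "GTP binding" = gtp_d <= lattice$ligand_cutoff,
    "longitudinal" = !is.na(dist_of(interface_residues(nbhd, "longitudinal"))),
    "lateral" = !is.na(dist_of(interface_residues(nbhd, "lateral"))),
    "intradimer" = !is.na(dist_of(interface_residues(nbhd, "intradimer"))))
  dists <- list(
    "GTP binding" = ifelse(is.finite(gtp_d), gtp_d, NA_real_),
    "longitudinal" = dist_of(interface_residues(nbhd, "longitudinal")),
    "lateral" = dist_of(interface_residues(nbhd, "lateral")),
    "intradimer" = dist_of(interface_residues(nbhd, "intradimer")))

  exposure <- relative_exposure(model, rules$exposure_radius)
  orient <- surface_orientation(model, lattice$axis_point, lattice$axis_dir,
                                exposure = exposure,
                                burial_threshold = rules$burial_threshold)
  member[["MAP binding"]] <- unname(orient[rkey] == "outer")
  member[["lumen"]] <- unname(orient[rkey] == "luminal")

  domain <- rep("other", n)
  evidence <- rep("", n)
  for (i in seq_len(n)) {
    ev <- character(0)
    for (lab in rules$precedence) {
      if (isTRUE(member[[lab]][i])) {
        if (domain[i] == "other") domain[i] <- lab
        ev <- c(ev, if (lab %in% names(dists)) {
          sprintf("%s:d=%.2f", lab, dists[[lab]][i])
        } else {
          sprintf("%s:exposure=%.2f", lab, exposure[rkey[i]])
        })
      }
    }
    evidence[i] <- paste(ev, collapse = ";")
  }

  out <- data.frame(chain = res$chain, resno = res$resno, aa = res$aa,
                    ss3 = res$ss3, domain = domain, evidence = evidence,
                    stringsAsFactors = FALSE)
  counts <- table(factor(out$domain, levels = DOMAIN_LEVELS))
  stopifnot(sum(counts) == n)  # partition is total
  structure(out, counts = counts, rules = rules,
            class = c("domain_partition", "data.frame"))
}

#' @export
print.domain_partition <- function(x, ...) {
  cat(sprintf("Functional-domain partition of %d residues\n", nrow(x)))
  print(attr(x, "counts"))
  invisible(x)
}

#' @export
summary.domain_partition <- function(object, ...) {
  counts <- attr(object, "counts")
  data.frame(domain = names(counts), count = as.integer(counts),
             fraction = as.integer(counts) / nrow(object))
}

#' Per-chain label map from a partition
#'
#' @param partition a `domain_partition`.
#' @param chain chain id; labels are keyed by residue number of that chain.
#' @return Named character vector, residue number to domain label.
#' @export
partition_labels <- function(partition, chain) {
  stopifnot(inherits(partition, "domain_partition"))
  sub <- partition[partition$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("no residues on chain %s", chain))
  stats::setNames(sub$domain, sub$resno)
}

#' Write a partition as TSV
#'
#' @param partition a `domain_partition`.
#' @param path output path.
#' @param header_lines optional comment lines (prefixed `#`) written first.
#' @export
write_partition <- function(partition, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(as.data.frame(partition), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
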