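# Residue-level structure model: reading, secondary-structure annotation,
# and category compositions.

SS_LEVELS <- c("helix", "sheet", "loop")
PHENOTYPE_LEVELS <- c("lissencephaly", "microlissencephaly", "pachygyria",
                      "polymicrogyria", "not_available")
CLINICAL_PHENOTYPES <- PHENOTYPE_LEVELS[1:4]

#' Reduce DSSP secondary-structure codes to three classes
#'
#' Standard eight-to-three reduction: H, G, I become `helix`; E, B become
#' `sheet`; everything else (including blanks) becomes `loop`. Inputs already
#' in the three-class vocabulary pass through unchanged.
#'
#' @param x character vector of DSSP codes or three-class labels.
#' @return Character vector over `c("helix", "sheet", "loop")`.
#' @examples
#' dssp3(c("H", "G", "E", "B", "T", "S", "-"))
#' @export
dssp3 <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% SS_LEVELS, x,
         ifelse(toupper(x) %in% c("H", "G", "I"), "helix",
         ifelse(toupper(x) %in% c("E", "B"), "sheet", "loop")))
  out
}

new_structure_model <- function(atoms, residues, chain_roles, ligands) {
  structure(list(atoms = atoms, residues = residues,
                 chain_roles = chain_roles, ligands = ligands),
            class = "structure_model")
}

validate_structure_model <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  if (nrow(res) == 0L) stop("structure model contains zero residues")
  key <- paste(res$chain, res$resno)
  if (anyDuplicated(key)) stop("duplicate (chain, residue number) in model")
  if (any(res$resno < 1L)) stop("residue numbers must be >= 1")
  if (!all(res$aa %in% AA_ONE)) stop("non-canonical residue in model")
  if (!all(res$chain %in% names(model$chain_roles))) {
    stop("residue belongs to an undeclared chain")
  }
  if (!all(model$chain_roles %in% c("alpha", "beta"))) {
    stop("chain roles must be 'alpha' or 'beta'")
  }
  akey <- paste(model$atoms$chain, model$atoms$resno)
  if (!all(key %in% akey)) stop("residue without atoms in model")
  if (!all(is.finite(as.matrix(model$atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  invisible(model)
}

#' Read a tubulin heterodimer structure into a residue-level model
#'
#' Parses a PDB or mmCIF file with bio3d, keeps heavy atoms of the 20
#' canonical amino acids on the declared chains, resolves alternate locations
#' by highest occupancy, and tags nucleotide ligands with their binding site.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param chain_roles named character vector mapping chain id to
#'   `"alpha"`/`"beta"`, e.g. `c(A = "alpha", B = "beta")`.
#' @param ligand_sites optional named character vector mapping a chain id to a
#'   site tag in `c("N-site", "E-site", "other")`; nucleotide HETATM groups on
#'   that chain receive the tag. Untagged ligands are `"other"`.
#' @param quiet suppress dropped-residue messages.
#' @return A `structure_model`: residue table (chain, resno, aa, ss3), heavy
#'   atom table with coordinates in Angstrom, chain roles, and tagged ligands.
#'   Secondary structure is `NA` until [attach_secondary_structure()] is
#'   called.
#' @export
read_structure <- function(path, chain_roles, ligand_sites = NULL,
                           quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("structure file '%s' does not exist", path))
  if (is.null(names(chain_roles)) || !all(nzchar(names(chain_roles)))) {
    stop("chain_roles must be a named vector, names are chain ids")
  }
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (any(nzchar(prot$insert))) {
    stop("insertion codes are not supported")
  }
  for (ch in names(chain_roles)) {
    if (!ch %in% prot$chain) stop(sprintf("chain %s absent", ch))
  }
  undeclared <- setdiff(unique(prot$chain), names(chain_roles))
  if (length(undeclared) && !quiet) {
    message("dropping undeclared chain(s): ", paste(undeclared, collapse = ", "))
  }
  prot <- prot[prot$chain %in% names(chain_roles), , drop = FALSE]
  noncanon <- unique(prot$resid[!prot$resid %in% names(AA_THREE_TO_ONE)])
  if (length(noncanon)) {
    if (!quiet) {
      warning("dropping non-canonical residue(s): ",
              paste(noncanon, collapse = ", "), call. = FALSE)
    }
    prot <- prot[prot$resid %in% names(AA_THREE_TO_ONE), , drop = FALSE]
  }
  # drop hydrogens
  elesy <- prot$elesy
  is_h <- (!is.na(elesy) & toupper(elesy) == "H") |
    ((is.na(elesy) | !nzchar(elesy)) & grepl("^[0-9]*H", prot$elety))
  prot <- prot[!is_h, , drop = FALSE]
  # altloc: keep the highest-occupancy conformer per residue
  prot$alt[is.na(prot$alt)] <- ""
  if (any(nzchar(prot$alt))) {
    keep <- rep(TRUE, nrow(prot))
    rkey <- paste(prot$chain, prot$resno)
    for (k in unique(rkey[nzchar(prot$alt)])) {
      idx <- which(rkey == k & nzchar(prot$alt))
      occ <- tapply(prot$o[idx], prot$alt[idx], sum)
      best <- names(occ)[which.max(occ)]
      keep[idx[prot$alt[idx] != best]] <- FALSE
    }
    prot <- prot[keep, , drop = FALSE]
  }
  if (nrow(prot) == 0L) stop("zero residues after filtering")
  atoms <- data.frame(chain = prot$chain, resno = as.integer(prot$resno),
                      elety = prot$elety,
                      x = prot$x, y = prot$y, z = prot$z,
                      stringsAsFactors = FALSE)
  ord <- order(match(atoms$chain, names(chain_roles)), atoms$resno)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  first <- !duplicated(paste(atoms$chain, atoms$resno))
  aa3 <- prot$resid[ord][first]
  residues <- data.frame(chain = atoms$chain[first],
                         resno = atoms$resno[first],
                         aa = unname(AA_THREE_TO_ONE[aa3]),
                         ss3 = NA_character_,
                         stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  # ligands: non-water HETATM groups
  het <- at[at$type == "HETATM" & !at$resid %in% c("HOH", "WAT", "DOD"), ,
            drop = FALSE]
  ligands <- list()
  if (nrow(het)) {
    gkey <- paste(het$chain, het$resno, het$resid, sep = ":")
    for (g in unique(gkey)) {
      idx <- gkey == g
      ch <- het$chain[idx][1]
      site <- "other"
      if (!is.null(ligand_sites) && ch %in% names(ligand_sites)) {
        site <- unname(ligand_sites[[ch]])
      }
      if (!site %in% c("N-site", "E-site", "other")) {
        stop(sprintf("unknown ligand site tag '%s'", site))
      }
      ligands[[length(ligands) + 1L]] <- list(
        name = het$resid[idx][1], chain = ch, site = site,
        atoms = data.frame(elety = het$elety[idx],
                           x = het$x[idx], y = het$y[idx], z = het$z[idx],
                           stringsAsFactors = FALSE))
    }
  }
  model <- new_structure_model(atoms, residues, chain_roles, ligands)
  validate_structure_model(model)
  model
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Tubulin structure model\n")
  for (ch in names(x$chain_roles)) {
    cat(sprintf("  chain %s (%s): %d residues\n", ch, x$chain_roles[[ch]],
                sum(x$residues$chain == ch)))
  }
  if (length(x$ligands)) {
    for (lg in x$ligands) {
      cat(sprintf("  ligand %s on chain %s [%s], %d atoms\n",
                  lg$name, lg$chain, lg$site, nrow(lg$atoms)))
    }
  }
  nss <- sum(!is.na(x$residues$ss3))
  cat(sprintf("  secondary structure: %d/%d residues annotated\n",
              nss, nrow(x$residues)))
  invisible(x)
}

#' Attach a three-class secondary-structure annotation
#'
#' Joins a per-residue annotation table onto the model. Rows may use the
#' three-class vocabulary directly or DSSP codes (reduced via [dssp3()]).
#' Residues absent from the table default to `loop` (reported). An annotation
#' row that matches no residue, or conflicting duplicate rows, are errors.
#'
#' @param model a `structure_model`.
#' @param ss a data frame with columns `chain`, `resnum`, `ss3`, or the path
#'   to a tab-separated file with those columns.
#' @param quiet suppress the defaulted-to-loop message.
#' @return The model with `ss3` filled in for every residue.
#' @export
attach_secondary_structure <- function(model, ss, quiet = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (is.character(ss) && length(ss) == 1L) {
    if (!file.exists(ss)) stop(sprintf("annotation file '%s' does not exist", ss))
    ss <- utils::read.delim(ss, stringsAsFactors = FALSE, comment.char = "#")
  }
  req <- c("chain", "resnum", "ss3")
  if (!all(req %in% names(ss))) {
    stop("annotation table needs columns chain, resnum, ss3")
  }
  ss <- data.frame(chain = as.character(ss$chain),
                   resnum = as.integer(ss$resnum),
                   ss3 = dssp3(ss$ss3), stringsAsFactors = FALSE)
  key <- paste(ss$chain, ss$resnum)
  if (anyDuplicated(key)) {
    dup <- ss[key %in% key[duplicated(key)], , drop = FALSE]
    if (nrow(unique(dup)) != length(unique(paste(dup$chain, dup$resnum)))) {
      stop("conflicting duplicate annotation rows")
    }
    ss <- ss[!duplicated(key), , drop = FALSE]
    key <- paste(ss$chain, ss$resnum)
  }
  rkey <- paste(model$residues$chain, model$residues$resno)
  missing <- setdiff(key, rkey)
  if (length(missing)) {
    stop(sprintf("annotation for non-existent residue(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  m <- match(rkey, key)
  model$residues$ss3 <- ss$ss3[m]
  n_default <- sum(is.na(model$residues$ss3))
  if (n_default > 0L) {
    model$residues$ss3[is.na(model$residues$ss3)] <- "loop"
    if (!quiet) {
      message(sprintf("%d unannotated residue(s) defaulted to loop", n_default))
    }
  }
  model
}

#' Category composition of a structure model
#'
#' Counts residues per category and derives the fractions `f_i` that define
#' the composition-proportional null used by the enrichment tests.
#'
#' @param model a `structure_model`.
#' @param category_of the labelling: `"ss"` to use the attached
#'   secondary-structure classes, a `domain_partition` from
#'   [assign_domains()], a function taking the residue table and returning a
#'   label per residue, or a character vector keyed by `"chain:resno"`.
#' @param chains restrict to these chain ids (default: all chains).
#' @return A `composition_table`: data frame with columns `category`,
#'   `count`, `fraction` and attribute `total_residues`.
#' @examples
#' \dontrun{
#' composition(model, "ss")
#' }
#' @export
composition <- function(model, category_of = "ss", chains = NULL) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  if (!is.null(chains)) res <- res[res$chain %in% chains, , drop = FALSE]
  if (nrow(res) == 0L) stop("no residues selected")
  lv <- NULL
  if (is.character(category_of) && length(category_of) == 1L &&
      category_of == "ss") {
    labels <- res$ss3
    lv <- SS_LEVELS
  } else if (inherits(category_of, "domain_partition")) {
    pdf <- as.data.frame(category_of)
    m <- match(paste(res$chain, res$resno), paste(pdf$chain, pdf$resno))
    labels <- pdf$domain[m]
    lv <- DOMAIN_LEVELS
  } else if (is.function(category_of)) {
    labels <- as.character(category_of(res))
    if (length(labels) != nrow(res)) {
      stop("labelling function must return one label per residue")
    }
  } else if (is.character(category_of) && !is.null(names(category_of))) {
    labels <- unname(category_of[paste(res$chain, res$resno, sep = ":")])
  } else {
    stop("unsupported category_of")
  }
  if (anyNA(labels)) {
    bad <- res[is.na(labels), , drop = FALSE]
    stop(sprintf("unlabeled residue(s), e.g. %s:%d",
                 bad$chain[1], bad$resno[1]))
  }
  if (is.null(lv)) lv <- sort(unique(labels))
  counts <- table(factor(labels, levels = lv))
  out <- data.frame(category = lv, count = as.integer(counts),
                    fraction = as.numeric(counts) / nrow(res),
                    stringsAsFactors = FALSE)
  attr(out, "total_residues") <- nrow(res)
  class(out) <- c("composition_table", "data.frame")
  out
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("Residue composition (n = %d)\n", attr(x, "total_residues")))
  df <- data.frame(category = x$category, count = x$count,
                   fraction = sprintf("%.4f", x$fraction))
  print(df, row.names = FALSE)
  invisible(x)
}
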