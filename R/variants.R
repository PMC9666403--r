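# Missense-variant tables: parsing, validation against the structure,
# phenotype labels, and per-category tabulation.

new_mutation_table <- function(df, props) {
  structure(df, props = props, class = c("mutation_table", "data.frame"))
}

#' Load a missense-variant table
#'
#' Reads a tab-separated table with columns `substitution` (one-letter
#' `R402C` or protein-HGVS-like `p.Arg402Cys` form) and `phenotype` (one of
#' lissencephaly, microlissencephaly, pachygyria, polymicrogyria, or
#' `not_available` when no clinical neuroimaging assessment is known). Extra
#' columns are preserved as metadata. Every substitution is parsed and
#' classified by property change; when a structure model is supplied the
#' wild-type residue of each row is cross-checked against the alpha-chain
#' sequence.
#'
#' @param x a file path or a data frame with the two required columns.
#' @param model optional `structure_model` for wild-type validation.
#' @param props a [property_table()] used for classification.
#' @return A `mutation_table` data frame with columns `substitution`,
#'   `wt_aa`, `position`, `mut_aa`, `phenotype`, one logical column per
#'   change flag, any metadata columns, and attribute `props`.
#' @export
load_variant_table <- function(x, model = NULL, props = property_table()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(sprintf("variant file '%s' does not exist", x))
    x <- utils::read.delim(x, stringsAsFactors = FALSE, comment.char = "#")
  }
  if (!is.data.frame(x) || !all(c("substitution", "phenotype") %in% names(x))) {
    stop("variant table needs columns substitution and phenotype")
  }
  bad_ph <- setdiff(unique(x$phenotype), PHENOTYPE_LEVELS)
  if (length(bad_ph)) {
    stop(sprintf("unknown phenotype label(s): %s; expected one of %s",
                 paste(bad_ph, collapse = ", "),
                 paste(PHENOTYPE_LEVELS, collapse = ", ")))
  }
  n <- nrow(x)
  wt <- character(n); pos <- integer(n); mut <- character(n)
  flags <- matrix(FALSE, n, 4,
                  dimnames = list(NULL, c("charge_loss_or_swap", "charge_gain",
                                          "hydrophobicity_change", "no_change")))
  for (i in seq_len(n)) {
    parsed <- parse_substitution(x$substitution[i])
    wt[i] <- parsed$wt_aa; pos[i] <- parsed$position; mut[i] <- parsed$mut_aa
    fl <- classify_substitution(wt[i], mut[i], props)
    flags[i, fl] <- TRUE
  }
  if (!is.null(model)) {
    stopifnot(inherits(model, "structure_model"))
    alpha_chains <- names(model$chain_roles)[model$chain_roles == "alpha"]
    res <- model$residues[model$residues$chain %in% alpha_chains, ,
                          drop = FALSE]
    seq_of <- stats::setNames(res$aa, res$resno)
    found <- unname(seq_of[as.character(pos)])
    bad <- which(is.na(found) | found != wt)
    if (length(bad)) {
      msgs <- vapply(bad, function(i) {
        sprintf("position %d: expected %s, structure has %s",
                pos[i], wt[i],
                ifelse(is.na(found[i]), "no residue", found[i]))
      }, character(1))
      stop("wild-type mismatch with structure:\n  ",
           paste(msgs, collapse = "\n  "))
    }
  }
  meta <- x[, setdiff(names(x), c("substitution", "phenotype")), drop = FALSE]
  out <- data.frame(substitution = x$substitution, wt_aa = wt, position = pos,
                    mut_aa = mut, phenotype = x$phenotype,
                    as.data.frame(flags), stringsAsFactors = FALSE)
  if (ncol(meta)) out <- cbind(out, meta)
  new_mutation_table(out, props)
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("Mutation table: %d missense variants\n", nrow(x)))
  ph <- table(factor(x$phenotype, levels = PHENOTYPE_LEVELS))
  for (m in names(ph)) cat(sprintf("  %s: %d\n", m, ph[[m]]))
  cat(sprintf("  clinically labeled: %d; without imaging data: %d\n",
              sum(x$phenotype != "not_available"),
              sum(x$phenotype == "not_available")))
  invisible(x)
}

#' Tabulate variants per residue category
#'
#' Counts variants per category using a position-to-category label map.
#' With `restrict = "clinical"`, variants labeled `not_available` are dropped
#' first (the published analyses use only the clinically assessed subset).
#'
#' @param table a `mutation_table`.
#' @param labels named character vector, residue position to category.
#' @param restrict `"all"` or `"clinical"`.
#' @param categories category levels for the output (default: the sorted
#'   unique values of `labels`).
#' @return Named integer vector of counts with attribute `dropped` (number of
#'   rows removed by the filter).
#' @export
tabulate_variants <- function(table, labels, restrict = c("all", "clinical"),
                              categories = NULL) {
  restrict <- match.arg(restrict)
  stopifnot(is.data.frame(table),
            all(c("position", "phenotype") %in% names(table)))
  kept <- table
  dropped <- 0L
  if (restrict == "clinical") {
    dropped <- sum(table$phenotype == "not_available")
    kept <- table[table$phenotype != "not_available", , drop = FALSE]
  }
  cat_of <- unname(labels[as.character(kept$position)])
  if (anyNA(cat_of)) {
    stop(sprintf("variant position %s outside the labeled range",
                 kept$position[which(is.na(cat_of))[1]]))
  }
  if (is.null(categories)) categories <- sort(unique(unname(labels)))
  counts <- table(factor(cat_of, levels = categories))
  out <- stats::setNames(as.integer(counts), categories)
  attr(out, "dropped") <- dropped
  out
}
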