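# Amino-acid chemistry tables and the substitution-change taxonomy.

#' @keywords internal
AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @keywords internal
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Kyte-Doolittle hydropathy index; positive values mark the hydrophobic set.
#' @keywords internal
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' Amino-acid property table
#'
#' Defines the side-chain chemistry used to classify substitutions: a charge
#' class per residue (aspartate/glutamate negative; lysine/arginine positive;
#' histidine neutral by default, switchable because its pKa is near 6) and a
#' hydropathy scale whose positive entries form the hydrophobic set.
#'
#' @param histidine_positive logical; treat histidine as positively charged.
#' @param hydropathy named numeric vector over the 20 canonical one-letter
#'   codes. Defaults to the Kyte-Doolittle index.
#' @param hydrophobic_cutoff residues with hydropathy strictly above this value
#'   form the hydrophobic set. Default 0.
#' @return An object of class `property_table` with elements `charge_of`
#'   (named character, `"positive"`/`"negative"`/`"neutral"`), `hydropathy_of`,
#'   `hydrophobic_set`, and the options used.
#' @examples
#' props <- property_table()
#' props$charge_of["R"]
#' props$hydrophobic_set
#' @export
property_table <- function(histidine_positive = FALSE,
                           hydropathy = KD_HYDROPATHY,
                           hydrophobic_cutoff = 0) {
  if (!all(AA_ONE %in% names(hydropathy))) {
    stop("hydropathy table must cover all 20 canonical amino acids")
  }
  hydropathy <- hydropathy[AA_ONE]
  charge <- stats::setNames(rep("neutral", length(AA_ONE)), AA_ONE)
  charge[c("D", "E")] <- "negative"
  charge[c("K", "R")] <- "positive"
  if (isTRUE(histidine_positive)) charge["H"] <- "positive"
  structure(
    list(charge_of = charge,
         hydropathy_of = hydropathy,
         hydrophobic_set = names(hydropathy)[hydropathy > hydrophobic_cutoff],
         histidine_positive = isTRUE(histidine_positive),
         hydrophobic_cutoff = hydrophobic_cutoff),
    class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("Amino-acid property table\n")
  cat("  charged:", paste0(names(x$charge_of)[x$charge_of != "neutral"],
                           " (", x$charge_of[x$charge_of != "neutral"], ")",
                           collapse = ", "), "\n")
  cat("  hydrophobic set:", paste(x$hydrophobic_set, collapse = " "), "\n")
  invisible(x)
}

#' Parse a protein substitution string
#'
#' Accepts the compact one-letter form used in the tubulinopathy literature
#' (e.g. `"R402C"`) and the protein-HGVS-like three-letter form
#' (e.g. `"p.Arg402Cys"`).
#'
#' @param text a single non-empty substitution string.
#' @return A list with elements `wt_aa`, `position` (integer, author
#'   numbering) and `mut_aa`, all canonical one-letter codes.
#' @examples
#' parse_substitution("R402C")
#' parse_substitution("p.Val409Ile")
#' @export
parse_substitution <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("substitution must be a single non-empty string")
  }
  token <- trimws(text)
  one <- "^([A-Za-z])([0-9]+)([A-Za-z])$"
  three <- "^p\\.?([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$"
  if (grepl(one, token)) {
    wt <- toupper(sub(one, "\\1", token))
    mut <- toupper(sub(one, "\\3", token))
    pos <- as.integer(sub(one, "\\2", token))
  } else if (grepl(three, token)) {
    wt3 <- toupper(sub(three, "\\1", token))
    mut3 <- toupper(sub(three, "\\3", token))
    pos <- as.integer(sub(three, "\\2", token))
    if (!wt3 %in% names(AA_THREE_TO_ONE)) {
      stop(sprintf("unknown residue code '%s' in substitution '%s'", wt3, token))
    }
    if (!mut3 %in% names(AA_THREE_TO_ONE)) {
      stop(sprintf("unknown residue code '%s' in substitution '%s'", mut3, token))
    }
    wt <- unname(AA_THREE_TO_ONE[wt3])
    mut <- unname(AA_THREE_TO_ONE[mut3])
  } else {
    stop(sprintf("cannot parse substitution '%s'", token))
  }
  if (!wt %in% AA_ONE) {
    stop(sprintf("unknown residue code '%s' in substitution '%s'", wt, token))
  }
  if (!mut %in% AA_ONE) {
    stop(sprintf("unknown residue code '%s' in substitution '%s'", mut, token))
  }
  if (wt == mut) {
    stop(sprintf("silent substitution '%s': wild-type and mutant are identical",
                 token))
  }
  if (pos < 1L) stop(sprintf("position must be >= 1 in substitution '%s'", token))
  list(wt_aa = wt, position = pos, mut_aa = mut)
}

#' Classify a missense substitution by amino-acid-property change
#'
#' Assigns the four-way (non-exclusive) change taxonomy used for
#' tubulinopathy variants: loss of charge or charge swap; gain of charge;
#' loss or gain of hydrophobicity; or no change in charge or hydrophobicity.
#' The first two are mutually exclusive by construction; the hydrophobicity
#' flag may co-occur with either; `no_change` fires exactly when no other
#' flag does.
#'
#' @param wt_aa,mut_aa canonical one-letter codes, distinct.
#' @param props a [property_table()].
#' @return Character vector of flags, a subset of
#'   `c("charge_loss_or_swap", "charge_gain", "hydrophobicity_change",
#'   "no_change")`, never empty.
#' @examples
#' classify_substitution("E", "K")  # charge swap
#' classify_substitution("V", "I")  # no property change
#' classify_substitution("R", "C")  # loses charge, gains hydrophobicity
#' @export
classify_substitution <- function(wt_aa, mut_aa, props = property_table()) {
  if (!inherits(props, "property_table")) stop("props must be a property_table")
  for (aa in c(wt_aa, mut_aa)) {
    if (!is.character(aa) || length(aa) != 1L || !aa %in% AA_ONE) {
      stop(sprintf("'%s' is not a canonical one-letter amino-acid code", aa))
    }
  }
  if (wt_aa == mut_aa) stop("wild-type and mutant residues are identical")
  chg <- props$charge_of
  wt_charged <- chg[[wt_aa]] != "neutral"
  mut_charged <- chg[[mut_aa]] != "neutral"
  flags <- character(0)
  if (wt_charged && (!mut_charged || chg[[mut_aa]] != chg[[wt_aa]])) {
    flags <- c(flags, "charge_loss_or_swap")
  }
  if (!wt_charged && mut_charged) {
    flags <- c(flags, "charge_gain")
  }
  if (xor(wt_aa %in% props$hydrophobic_set, mut_aa %in% props$hydrophobic_set)) {
    flags <- c(flags, "hydrophobicity_change")
  }
  if (length(flags) == 0L) flags <- "no_change"
  flags
}
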