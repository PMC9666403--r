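# Pipeline orchestration: configuration, provenance, report rendering.

tubvar_input_error <- function(msg) {
  stop(structure(class = c("tubvar_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Assemble a pipeline configuration
#'
#' A configuration is a plain list (readable from a single JSON file) naming
#' the input paths and analysis options. Missing options take the documented
#' defaults; unknown fields are an error so typos do not silently change an
#' analysis.
#'
#' @param x a JSON file path or a list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) tubvar_input_error(
      sprintf("config file '%s' does not exist", x))
    x <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  }
  defaults <- list(
    structure = NULL, ss_table = NULL, variants = NULL, lattice = NULL,
    output_dir = ".",
    chain_roles = c(A = "alpha", B = "beta"),
    ligand_sites = c(A = "N-site", B = "E-site"),
    burial_threshold = 0.15, exposure_radius = 9.5,
    background = "residues", alpha = 0.05, histidine_positive = FALSE,
    seed = 1, replicates = 100, fold = 1,
    target_phenotype = NULL, target_category = NULL)
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    tubvar_input_error(sprintf("unknown config field(s): %s",
                               paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, x)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    tubvar_input_error("alpha must be in (0, 1)")
  }
  cfg$chain_roles <- unlist(cfg$chain_roles)
  cfg$ligand_sites <- unlist(cfg$ligand_sites)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  # hash the analysis-relevant fields only, so the same analysis written to
  # two directories carries the same provenance
  cfg <- unclass(cfg)
  cfg$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(cfg) {
  c(sprintf("tubvar %s", as.character(utils::packageVersion("tubvar"))),
    sprintf("config md5 %s", config_hash(cfg)),
    sprintf("seed %d", as.integer(cfg$seed)))
}

require_path <- function(path, what) {
  if (is.null(path)) tubvar_input_error(sprintf("config must name a %s", what))
  if (!file.exists(path)) {
    tubvar_input_error(sprintf("%s '%s' does not exist", what, path))
  }
  path
}

load_annotated_model <- function(cfg) {
  model <- read_structure(require_path(cfg$structure, "structure file"),
                          chain_roles = cfg$chain_roles,
                          ligand_sites = cfg$ligand_sites, quiet = TRUE)
  model <- attach_secondary_structure(
    model, require_path(cfg$ss_table, "secondary-structure table"),
    quiet = TRUE)
  model
}

#' Annotate a structure: domain partition and compositions
#'
#' Reads the structure, attaches secondary structure, partitions residues
#' into functional domains under the lattice model, and writes
#' `partition.tsv` (one row per residue) and `composition.json` (secondary
#' structure and domain compositions) to the output directory, each with a
#' provenance header.
#'
#' @param config a [pipeline_config()], list, or JSON path.
#' @return Invisibly, a list with `partition`, `composition_ss`,
#'   `composition_domain` and the output `files`.
#' @export
pipeline_annotate <- function(config) {
  cfg <- pipeline_config(config)
  model <- load_annotated_model(cfg)
  lattice <- read_lattice_spec(require_path(cfg$lattice, "lattice file"))
  rules <- domain_rules(burial_threshold = cfg$burial_threshold,
                        exposure_radius = cfg$exposure_radius)
  part <- assign_domains(model, lattice, rules)
  comp_ss <- composition(model, "ss")
  comp_dom <- composition(model, part)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(partition = file.path(cfg$output_dir, "partition.tsv"),
                composition = file.path(cfg$output_dir, "composition.json"))
  write_partition(part, files$partition, header_lines = provenance_header(cfg))
  comp_json <- list(
    provenance = as.list(provenance_header(cfg)),
    secondary_structure = as.data.frame(comp_ss),
    functional_domain = as.data.frame(comp_dom),
    total_residues = attr(comp_ss, "total_residues"))
  writeLines(jsonlite::toJSON(comp_json, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), files$composition)
  invisible(list(partition = part, composition_ss = comp_ss,
                 composition_domain = comp_dom, model = model,
                 files = files))
}

#' Run the enrichment analysis and render the report
#'
#' Runs the full scan over both classification schemes (secondary structure
#' and functional domain) for the alpha chain and writes a wide
#' Table-1-style report (`report.tsv`: scheme-grouped category rows by
#' phenotype columns, p-values printed to two decimals with values below
#' 0.005 shown as `<0.01`), a long-format table (`report_long.tsv`, full
#' precision), and a JSON twin with provenance (`report.json`).
#'
#' @param config a [pipeline_config()], list, or JSON path.
#' @return Invisibly, a list with both `enrich_scan` objects, the rendered
#'   wide report, and the output `files`.
#' @export
pipeline_enrich <- function(config) {
  cfg <- pipeline_config(config)
  ann <- pipeline_annotate(cfg)
  model <- ann$model
  variants <- load_variant_table(
    require_path(cfg$variants, "variant table"), model = model,
    props = property_table(histidine_positive = cfg$histidine_positive))
  if (!any(variants$phenotype != "not_available")) {
    tubvar_input_error("no clinically labeled variants in the table")
  }
  alpha_chain <- names(cfg$chain_roles)[cfg$chain_roles == "alpha"][1]
  ss_labels <- stats::setNames(
    model$residues$ss3[model$residues$chain == alpha_chain],
    model$residues$resno[model$residues$chain == alpha_chain])
  dom_labels <- partition_labels(ann$partition, alpha_chain)
  comp_ss <- composition(model, "ss", chains = alpha_chain)
  comp_dom <- composition(model, ann$partition, chains = alpha_chain)
  scan_ss <- enrichment_scan(variants, ss_labels, comp_ss,
                             background = cfg$background, alpha = cfg$alpha)
  scan_dom <- enrichment_scan(variants, dom_labels, comp_dom,
                              background = cfg$background, alpha = cfg$alpha)
  wide <- rbind(
    data.frame(scheme = "Secondary structure",
               category = comp_ss$category,
               summary(scan_ss)$p_matrix, check.names = FALSE),
    data.frame(scheme = "Functional domain",
               category = comp_dom$category,
               summary(scan_dom)$p_matrix, check.names = FALSE))
  wide_disp <- wide
  for (m in CLINICAL_PHENOTYPES) wide_disp[[m]] <- format_p(wide[[m]])
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(report = file.path(cfg$output_dir, "report.tsv"),
                long = file.path(cfg$output_dir, "report_long.tsv"),
                json = file.path(cfg$output_dir, "report.json"))
  hdr <- provenance_header(cfg)
  con <- file(files$report, "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(wide_disp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  long <- rbind(cbind(scheme = "Secondary structure", scan_ss$results),
                cbind(scheme = "Functional domain", scan_dom$results))
  con <- file(files$long, "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  out_json <- list(
    provenance = as.list(hdr),
    options = list(background = cfg$background, alpha = cfg$alpha,
                   histidine_positive = cfg$histidine_positive,
                   burial_threshold = cfg$burial_threshold),
    n_total = scan_ss$n_total, n_clinical = scan_ss$n_clinical,
    n_dropped = scan_ss$n_dropped,
    gof = list(
      secondary_structure = list(
        statistic = unname(scan_ss$gof$statistic),
        df = unname(scan_ss$gof$parameter), p = scan_ss$gof$p.value),
      functional_domain = list(
        statistic = unname(scan_dom$gof$statistic),
        df = unname(scan_dom$gof$parameter), p = scan_dom$gof$p.value)),
    cells = long)
  writeLines(jsonlite::toJSON(out_json, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE), files$json)
  invisible(list(scan_ss = scan_ss, scan_dom = scan_dom, report = wide_disp,
                 files = files))
}

#' Run a simulation study from a configuration
#'
#' Generates a toy lattice from the config seed, uses its planted domain
#' labels, and drives [run_simulation_study()]; the per-cell rejection
#' summary is written as TSV with a provenance header.
#'
#' @param config a [pipeline_config()], list, or JSON path.
#' @return Invisibly, the `simulation_summary` and the output file path.
#' @export
pipeline_simulate <- function(config) {
  cfg <- pipeline_config(config)
  if (cfg$replicates < 1) tubvar_input_error("replicates must be >= 1")
  toy <- make_toy_lattice(toy_lattice_params(seed = cfg$seed))
  labels <- stats::setNames(toy$truth$domain[toy$truth$chain == "A"],
                            toy$truth$resno[toy$truth$chain == "A"])
  comp <- composition(toy$model,
                      stats::setNames(toy$truth$domain,
                                      paste(toy$truth$chain, toy$truth$resno,
                                            sep = ":")),
                      chains = "A")
  sim <- run_simulation_study(
    labels, comp, alpha_sequence(toy$model),
    target_phenotype = cfg$target_phenotype,
    target_category = cfg$target_category,
    fold = cfg$fold, replicates = cfg$replicates, alpha = cfg$alpha,
    background = cfg$background, seed = cfg$seed)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cfg$output_dir, "simulation.tsv")
  con <- file(path, "w")
  writeLines(paste0("# ", provenance_header(cfg)), con)
  utils::write.table(as.data.frame(sim), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(list(summary = sim, file = path))
}

#' Materialize the default fixture set
#'
#' Writes the toy lattice files (structure, ground truth, secondary
#' structure, lattice JSON), an alpha-tubulin-like 451-residue
#' secondary-structure annotation, and a null variant table for the toy
#' alpha chain.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_set <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toy <- make_toy_lattice(toy_lattice_params(seed = seed), dir = dir)
  ss451 <- file.path(dir, "tuba1a_like_ss.tsv")
  make_ss_annotation(n = 451, seed = seed, path = ss451)
  labels <- stats::setNames(toy$truth$domain[toy$truth$chain == "A"],
                            toy$truth$resno[toy$truth$chain == "A"])
  var_path <- file.path(dir, "synthetic_variants.tsv")
  # cohort-scale null table: 53 clinically labeled + 66 without imaging data
  make_variant_table(labels, alpha_sequence(toy$model),
                     n_per_phenotype = c(lissencephaly = 13,
                                         microlissencephaly = 13,
                                         pachygyria = 13,
                                         polymicrogyria = 14,
                                         not_available = 66),
                     seed = seed, path = var_path)
  invisible(c(toy$files, list(ss451 = ss451, variants = var_path)))
}
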