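#' Build and validate a pipeline run configuration
#'
#' Defaults follow the field's conventional thresholds: 10-nt merge window,
#' |log2FC| >= 1 with q <= 0.05 for DEC calls, p <= 0.05 for correlation and
#' enrichment, 100/500 RPM expression bins, 63-nt minimum ORF, target-score
#' cutoff 4.
#'
#' @param seed master seed for the synthetic study.
#' @param n_genes,n_circ,n_mirnas synthetic study scale.
#' @param tolerance merge window (nt).
#' @param presence_rule detection rule, see [detect_expressed()].
#' @param lfc_min,q_max DEC thresholds.
#' @param target_cutoff miRNA target penalty cutoff.
#' @param min_orf_nt minimum ORF length.
#' @param cor_p_max correlation significance threshold.
#' @param beta soft-threshold power for the co-expression network (NULL =
#'   choose by scale-free fit).
#' @param min_module_size,cut_height,hub_k module detection and hub
#'   parameters.
#' @param ... extra arguments forwarded to [simulate_study()].
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_genes = 40L, n_circ = 150L,
                       n_mirnas = 20L, tolerance = 10L,
                       presence_rule = "any_replicate",
                       lfc_min = 1, q_max = 0.05, target_cutoff = 4,
                       min_orf_nt = 63L, cor_p_max = 0.05, beta = NULL,
                       min_module_size = 5L, cut_height = 0.99, hub_k = 25L,
                       ...) {
  cfg <- list(seed = seed, n_genes = n_genes, n_circ = n_circ,
              n_mirnas = n_mirnas, tolerance = tolerance,
              presence_rule = presence_rule, lfc_min = lfc_min,
              q_max = q_max, target_cutoff = target_cutoff,
              min_orf_nt = min_orf_nt, cor_p_max = cor_p_max, beta = beta,
              min_module_size = min_module_size, cut_height = cut_height,
              hub_k = hub_k, sim_args = list(...))
  stopifnot_scalar_count(cfg$seed, "seed", min = 0L)
  stopifnot_scalar_count(cfg$n_circ, "n_circ")
  if (cfg$tolerance < 0 || cfg$lfc_min < 0 || cfg$q_max <= 0 || cfg$q_max > 1)
    stop("invalid thresholds in configuration", call. = FALSE)
  if (!cfg$presence_rule %in% c("any_replicate", "mean_positive", "majority"))
    stop("unknown presence rule", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full circRNA heterosis pipeline on a synthetic study
#'
#' Simulates a labelled study, then chains every stage: caller-call merging,
#' origin classification, parent-gene assignment, RPM quantification,
#' presence calls, per-F1 MPV tests with additivity/Stupar/SPE
#' classification, parental and F1-high-vs-low DEC comparisons with the
#' co-DEC decomposition, miRNA target scanning, circular ORF detection,
#' circRNA/parent-gene correlation, and co-expression modules with
#' module-trait correlations and hubs. When `out_dir` is given, all stage
#' tables are written as TSV along with a YAML run manifest.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with the stage outputs (`sim`, `catalog`, `classified`,
#'   `parent_map`, `rpm`, `presence`, `heterosis`, `dec`, `summary`,
#'   `targets`, `orfs`, `coding`, `correlation`, `modules`) and a `report`
#'   list of the headline summary tables.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  sim <- do.call(simulate_study,
                 c(list(seed = config$seed, n_genes = config$n_genes,
                        n_circ = config$n_circ, n_mirnas = config$n_mirnas),
                   config$sim_args))
  design <- sim$design

  catalog <- merge_calls(sim$calls$calls_A, sim$calls$calls_B,
                         tolerance = config$tolerance)
  classified <- classify_origin(catalog$table, sim$annotation)
  parent_map <- assign_parent_genes(classified)

  rpm <- rpm_normalize(catalog$counts, design$mapped_reads)
  presence <- detect_expressed(rpm, design, config$presence_rule)

  het <- heterosis_calls(catalog$counts, design,
                         presence_rule = config$presence_rule,
                         lfc_min = config$lfc_min, q_max = config$q_max)

  parent_dec <- de_compare(catalog$counts, design, "MP", "FP",
                           lfc_min = config$lfc_min, q_max = config$q_max)
  high <- design_genotypes(design, "F1_high")
  low <- design_genotypes(design, "F1_low")
  pairs <- expand.grid(low = low[seq_len(min(2, length(low)))],
                       high = high[seq_len(min(2, length(high)))],
                       stringsAsFactors = FALSE)
  f1_dec <- lapply(seq_len(nrow(pairs)), function(i)
    de_compare(catalog$counts, design, pairs$low[i], pairs$high[i],
               lfc_min = config$lfc_min, q_max = config$q_max))
  names(f1_dec) <- sprintf("%s_vs_%s", pairs$low, pairs$high)

  summary_tables <- summarize_patterns(het, parent_dec, f1_dec)

  # function prediction on the merged catalog, using truth sequences matched
  # by representative coordinates (callers jitter coordinates slightly)
  seqs <- sim$truth$sequences
  cat_seqs <- stats::setNames(
    seqs[match_catalog_to_truth(classified, sim$truth)], classified$circ_id)
  cat_seqs <- cat_seqs[!is.na(names(cat_seqs)) & !is.na(cat_seqs)]
  hits <- find_targets(cat_seqs, sim$mirnas$mirnas,
                       cutoff = config$target_cutoff)
  target_summary <- summarize_targets(hits)
  orfs <- find_orfs_all(cat_seqs, min_orf_nt = config$min_orf_nt)
  coding <- coding_potential(orfs, names(cat_seqs))

  corr <- pair_correlation(rpm, sim$expression$gene_fpkm, parent_map$map,
                           p_max = config$cor_p_max)
  corr_summary <- summarize_correlation(corr)

  # co-expression on the DEC features (plus parental DECs), RPM scale
  dec_ids <- unique(c(
    unlist(lapply(f1_dec, function(d)
      d$feature_id[!is.na(d$direction) & d$direction != "ns"])),
    parent_dec$feature_id[!is.na(parent_dec$direction) &
                            parent_dec$direction != "ns"]))
  modules <- NULL
  if (length(dec_ids) >= 3 * config$min_module_size) {
    mat <- rpm[dec_ids, , drop = FALSE]
    beta <- config$beta %||% pick_beta(mat)$beta
    tom <- build_tom(mat, beta)
    assignments <- detect_modules(tom, config$min_module_size,
                                  config$cut_height)
    kept <- rownames(tom)
    eg <- module_eigengenes(mat[kept, , drop = FALSE], assignments)
    mt <- if (nrow(eg)) module_trait(eg, design) else NULL
    hubs <- lapply(setdiff(unique(assignments), "grey"), function(m)
      select_hubs(mat[kept, , drop = FALSE], assignments, m,
                  k = config$hub_k, beta = beta))
    names(hubs) <- setdiff(unique(assignments), "grey")
    modules <- list(beta = beta, assignments = assignments,
                    eigengenes = eg, module_trait = mt, hubs = hubs)
  }

  report <- list(
    catalog_size = nrow(classified),
    origin_proportions = prop.table(table(classified$origin_class)),
    expressed_counts = presence$expressed_counts,
    n_co_expressed = length(presence$co_expressed),
    additivity = summary_tables$additivity,
    stupar = summary_tables$stupar,
    spe = summary_tables$spe,
    spe_in_parent_dec = summary_tables$spe_in_parent_dec,
    co_dec = summary_tables$co_dec,
    target_totals = target_summary$totals,
    n_orf_circ = length(unique(orfs$circ_id)),
    correlation = corr_summary,
    n_modules = if (is.null(modules)) 0L
    else length(setdiff(unique(modules$assignments), "grey")))

  result <- list(sim = sim, catalog = catalog, classified = classified,
                 parent_map = parent_map, rpm = rpm, presence = presence,
                 heterosis = het,
                 dec = c(list(MP_vs_FP = parent_dec), f1_dec),
                 summary = summary_tables, targets = hits,
                 target_summary = target_summary, orfs = orfs,
                 coding = coding, correlation = corr,
                 correlation_summary = corr_summary, modules = modules,
                 report = report, config = config)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# match merged catalog entries back to planted truth circRNAs by coordinates
# (nearest within the merge window); returns truth indices or NA
match_catalog_to_truth <- function(classified, truth, tolerance = 10L) {
  vapply(seq_len(nrow(classified)), function(i) {
    cand <- which(truth$circ$chrom == classified$chrom[i] &
                    truth$circ$strand == classified$strand[i] &
                    abs(truth$circ$start - classified$start[i]) <= tolerance &
                    abs(truth$circ$end - classified$end[i]) <= tolerance)
    if (!length(cand)) return(NA_integer_)
    d <- abs(truth$circ$start[cand] - classified$start[i]) +
      abs(truth$circ$end[cand] - classified$end[i])
    cand[which.min(d)]
  }, integer(1))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write_tsv(df, file.path(out_dir, name))
  tsv(result$classified, "catalog.tsv")
  counts_df <- data.frame(circ_id = rownames(result$catalog$counts),
                          result$catalog$counts, check.names = FALSE)
  tsv(counts_df, "merged_counts.tsv")
  tsv(result$sim$design$samples, "design.tsv")
  tsv(result$heterosis, "heterosis_calls.tsv")
  for (nm in names(result$dec))
    tsv(result$dec[[nm]], sprintf("dec_%s.tsv", nm))
  tsv(result$targets, "target_hits.tsv")
  tsv(result$orfs, "orf_hits.tsv")
  tsv(result$coding, "coding_potential.tsv")
  tsv(result$correlation, "correlation.tsv")
  tsv(result$correlation_summary, "correlation_summary.tsv")
  tsv(result$summary$additivity, "summary_additivity.tsv")
  tsv(result$summary$stupar, "summary_stupar.tsv")
  tsv(result$summary$spe, "summary_spe.tsv")
  if (!is.null(result$summary$spe_in_parent_dec))
    tsv(result$summary$spe_in_parent_dec, "summary_spe_in_parent_dec.tsv")
  if (!is.null(result$summary$co_dec))
    tsv(result$summary$co_dec, "summary_co_dec.tsv")
  if (!is.null(result$modules)) {
    tsv(data.frame(feature_id = names(result$modules$assignments),
                   module = unname(result$modules$assignments)),
        "module_assignments.tsv")
  }
  manifest <- list(
    package = "circheterosis",
    version = as.character(utils::packageVersion("circheterosis")),
    seed = result$config$seed,
    parameters = result$config[setdiff(names(result$config), "sim_args")])
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
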