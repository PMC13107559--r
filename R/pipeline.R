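# One-command orchestration of the synthetic study analysis:
# simulate -> qc -> annotate -> classify -> diff -> atac -> integrate,
# with a validated config, per-stage record-count logging, and
# deterministic, provenance-stamped outputs (rerunning with the same
# config and seed reproduces every file byte for byte).

#' Default pipeline configuration
#'
#' Every threshold the analysis depends on is an explicit mandatory key;
#' validation refuses configs that omit one.
#'
#' @param seed master seed.
#' @return nested config list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    sim = list(),
    qc = list(min_distance = 10000, min_count = 4, count_rule = "max"),
    annotate = list(slack = 0, promoter_upstream = 1000,
                    promoter_downstream = 1000),
    classify = list(slack = 0, span_mode = "midpoint"),
    diff = list(pre = "untreated", post = "IAA", alpha = 0.05, min_lfc = 1,
                pseudocount = 1),
    atac = list(pre = "untreated", post = "IAA", alpha = 0.05, min_lfc = 1),
    integrate = list(pre = "untreated", post = "IAA", alpha = 0.05,
                     min_lfc = 1, test = "qlf", rescue_tolerance = 0.5)
  )
}

.required_keys <- list(
  qc = c("min_distance", "min_count", "count_rule"),
  annotate = c("slack", "promoter_upstream", "promoter_downstream"),
  classify = c("slack", "span_mode"),
  diff = c("pre", "post", "alpha", "min_lfc", "pseudocount"),
  atac = c("pre", "post", "alpha", "min_lfc"),
  integrate = c("pre", "post", "alpha", "min_lfc", "test",
                "rescue_tolerance")
)

#' Validate a pipeline configuration
#'
#' @param config nested config list or path to a JSON config file.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed)) stop("missing config key 'seed' (top level)")
  for (section in names(.required_keys)) {
    if (is.null(config[[section]]))
      stop("missing config section '", section, "'")
    miss <- setdiff(.required_keys[[section]], names(config[[section]]))
    if (length(miss))
      stop("missing config key '", miss[1], "' in section '", section, "'")
  }
  if (is.null(config$sim)) config$sim <- list()
  config
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' @param config config list or JSON path (see [default_config()]).
#' @param outdir output directory; created if needed.
#' @return invisibly, a list with all stage results, the summary, and the
#'   per-stage record-count log.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  stamp <- paste0("config=", hash, " seed=", config$seed)
  p <- function(f) file.path(outdir, f)
  log <- list(config_hash = hash, seed = config$seed, stages = list())

  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  study <- simulate_study(cfg, outdir = p("sim"))
  log$stages$simulate <- list(n_ctcf_loops = nrow(study$ctcf$loops),
                              n_interactions = nrow(study$interactions),
                              n_atac_windows = nrow(study$atac),
                              n_genes = nrow(study$gene_models))

  # --- qc ---
  qc1 <- filter_short_range(study$interactions,
                            min_distance = config$qc$min_distance)
  qc2 <- filter_low_count(qc1, min_count = config$qc$min_count,
                          rule = config$qc$count_rule)
  prom <- promoter_windows(study$gene_models,
                           upstream = config$annotate$promoter_upstream,
                           downstream = config$annotate$promoter_downstream,
                           chrom_sizes = cfg$genome)
  elements <- rbind(prom[c("chrom", "start", "end", "name")],
                    study$enhancers[c("chrom", "start", "end", "name")])
  qc3 <- merge_identical_element_loops(qc2, elements)
  log$stages$qc <- list(n_in = nrow(study$interactions),
                        removed_short_range = attr(qc1, "n_removed"),
                        removed_low_count = attr(qc2, "n_removed"),
                        merged = attr(qc3, "n_removed"),
                        n_out = nrow(qc3))
  write_bedpe(qc3, p("interactions_qc.bedpe"), stamp)

  # --- annotate ---
  anchors <- loop_anchors(qc3)
  labels <- label_anchors(anchors, study$ctcf$peaks, study$enhancers, prom,
                          slack = config$annotate$slack)
  itypes <- classify_interaction_types(qc3, labels)
  lf <- looping_fraction(study$h3k_sites, qc3,
                         slack = config$annotate$slack)
  cov_ctcf <- union_coverage(loop_span(study$ctcf$loops, "outer"),
                             cfg$genome)
  cov_h3k <- union_coverage(loop_span(qc3, "outer"), cfg$genome)
  write_tsv(itypes, p("interaction_types.tsv"), stamp)
  log$stages$annotate <- list(
    n_anchors = nrow(labels),
    looping = lf$n_looping, total_sites = lf$n_total,
    looping_fraction = lf$fraction,
    coverage_ctcf = cov_ctcf, coverage_h3k27ac = cov_h3k)

  # --- classify ---
  topo <- classify_topology(qc3, study$ctcf$loops,
                            slack = config$classify$slack,
                            span_mode = config$classify$span_mode)
  catdist <- category_distribution(topo)
  write_tsv(topo[setdiff(names(topo), "relations")],
            p("topology.tsv"), stamp)
  write_tsv(catdist, p("category_distribution.tsv"), stamp)
  log$stages$classify <- list(n_classified = nrow(topo))

  # --- diff ---
  diff <- call_differential(qc3, config$diff$pre, config$diff$post,
                            alpha = config$diff$alpha,
                            min_lfc = config$diff$min_lfc,
                            pseudocount = config$diff$pseudocount)
  class_report <- class_response_report(topo, diff)
  strat_cross <- stratify_by_ctcf_strength(topo, diff, "cross")
  cc_grid <- contain_cross_grid(topo, diff)
  write_tsv(diff, p("differential_interactions.tsv"), stamp)
  write_tsv(class_report, p("class_response.tsv"), stamp)
  write_tsv(strat_cross$table, p("cross_strength_strata.tsv"), stamp)
  write_tsv(cc_grid$grid, p("contain_cross_grid.tsv"), stamp)
  n_sig <- sum(diff$call != "unchanged")
  log$stages$diff <- list(
    n_tested = nrow(diff), n_up = sum(diff$call == "up"),
    n_down = sum(diff$call == "down"),
    affected = percent_report(n_sig, nrow(diff), 2)$label)

  # --- atac ---
  atac_diff <- call_differential_accessibility(
    study$atac, config$atac$pre, config$atac$post,
    alpha = config$atac$alpha, min_lfc = config$atac$min_lfc)
  down_idx <- which(atac_diff$call == "down")
  down_sites <- study$atac[down_idx, c("chrom", "start", "end", "name")]
  part <- partition_by_ctcf_overlap(down_sites, study$ctcf$peaks,
                                    study$ctcf$motifs)
  prom_down <- promoter_fraction_of_down_sites(down_sites, prom)
  deg_truth_genes <- study$truth$genes$gene_id[study$truth$genes$direction == "down"]
  mtd <- motif_tss_distance(study$ctcf$motifs, study$gene_models,
                            gene_subset = deg_truth_genes)
  write_tsv(atac_diff, p("atac_differential.tsv"), stamp)
  log$stages$atac <- list(
    n_windows = nrow(atac_diff),
    n_up = sum(atac_diff$call == "up"),
    n_down = sum(atac_diff$call == "down"),
    group1_fraction = part$overlap_fraction,
    promoter_sites = prom_down$n_promoter_sites,
    promoter_genes = prom_down$n_genes,
    motif_tss_median = mtd$median)

  # --- integrate ---
  counts <- study$expression$counts
  design <- study$expression$design
  degs <- call_degs(counts, design, config$integrate$pre,
                    config$integrate$post, alpha = config$integrate$alpha,
                    min_lfc = config$integrate$min_lfc,
                    test = config$integrate$test)
  deg_down <- degs$gene[degs$status == "down"]
  iaa_resp <- iaa_responsive_genes(counts, design,
                                   tolerance = config$integrate$rescue_tolerance)
  rescue <- classify_rescue(counts, design,
                            setdiff(deg_down, iaa_resp),
                            tolerance = config$integrate$rescue_tolerance)
  pflags <- flag_promoter_ctcf(prom, study$ctcf$peaks)
  loopy_genes <- genes_with_diff_interactions(diff, qc3, itypes, prom)
  mech <- partition_deg_by_mechanism(deg_down, pflags, loopy_genes)
  write_tsv(degs, p("degs.tsv"), stamp)
  write_tsv(rescue, p("rescue_classes.tsv"), stamp)
  write_tsv(mech, p("mechanism_partition.tsv"), stamp)
  log$stages$integrate <- list(
    n_deg_down = length(deg_down),
    n_iaa_responsive = length(iaa_resp),
    promoter_ctcf_fraction = percent_report(
      sum(deg_down %in% names(pflags)[pflags]),
      max(1, length(deg_down)))$label,
    mechanism = as.list(table(mech$mechanism)))

  summary <- list(
    category_distribution = catdist,
    class_response = class_report,
    cross_strength_strata = strat_cross$table,
    contain_cross_grid = cc_grid$grid,
    atac = log$stages$atac,
    integrate = log$stages$integrate)
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(list(study = study, qc = qc3, topology = topo,
                 interaction_types = itypes, diff = diff,
                 class_response = class_report, atac_diff = atac_diff,
                 degs = degs, rescue = rescue, mechanism = mech,
                 summary = summary, log = log))
}
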