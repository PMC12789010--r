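#' Build and validate a pipeline run configuration
#'
#' Collects input paths and parameters for [run_pipeline()] and validates
#' them eagerly (fail-fast): every declared path must exist and every
#' parameter must be in range before any computation starts. Stages are
#' enabled by the inputs they need; a stage whose inputs are absent is
#' skipped (or, if explicitly requested via `stages`, raises a validation
#' error).
#'
#' @param replicate_peaks list of BED/narrowPeak paths (replicate peak
#'   sets) or a list of `GRanges`.
#' @param chrom_sizes chromosome-sizes path or a [genome_layout()].
#' @param fasta FASTA path or `DNAStringSet` (motif scanning).
#' @param pwm_a,pwm_b PWM file paths (JASPAR/MEME) or `pwm` objects.
#' @param atac ATAC peak BED path or `GRanges`.
#' @param target_peaks BED path or `GRanges`: the fixed target set of the
#'   permutation overlap test.
#' @param genes gene-model path or data.frame (see [read_gene_models()]).
#' @param deg DEG table path or data.frame (`gene`, `log2fc`, `padj`).
#' @param stages optional character vector of required stage names (subset
#'   of `consensus`, `annotate`, `cooccur`, `spacing`, `permtest`,
#'   `accessibility`, `degcross`); absence of a required stage's inputs is
#'   an error.
#' @param min_support,promoter_halfwidth,max_gene_distance,scan_threshold,
#'   min_fold,max_padj,n_shuffles,min_bp pipeline parameters (see the
#'   stage functions).
#' @param seed integer seed, required because the permutation stage is
#'   stochastic.
#' @return a validated `run_config` list.
#' @export
run_config <- function(replicate_peaks = NULL, chrom_sizes = NULL,
                       fasta = NULL, pwm_a = NULL, pwm_b = NULL,
                       atac = NULL, target_peaks = NULL, genes = NULL,
                       deg = NULL, stages = NULL,
                       min_support = 2L, promoter_halfwidth = 1000L,
                       max_gene_distance = 1e5, scan_threshold = NULL,
                       min_fold = 1.5, max_padj = 0.05,
                       n_shuffles = 1000L, min_bp = 1L, seed) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1)
  check_path <- function(x, what) {
    if (is.character(x)) {
      missing <- x[!file.exists(x)]
      if (length(missing))
        stop("validation error: ", what, " path(s) do not exist: ",
             paste(missing, collapse = ", "))
    }
    x
  }
  if (!is.null(replicate_peaks) && is.list(replicate_peaks))
    lapply(replicate_peaks, function(p)
      if (is.character(p)) check_path(p, "replicate peak"))
  for (nm in c("chrom_sizes", "fasta", "pwm_a", "pwm_b", "atac",
               "target_peaks", "genes", "deg")) {
    v <- get(nm)
    if (is.character(v)) check_path(v, nm)
  }
  stopifnot(min_support >= 1, promoter_halfwidth > 0,
            max_gene_distance >= 0, min_fold > 1,
            max_padj > 0, max_padj <= 1, n_shuffles >= 1, min_bp >= 1)
  cfg <- list(replicate_peaks = replicate_peaks,
              chrom_sizes = chrom_sizes, fasta = fasta,
              pwm_a = pwm_a, pwm_b = pwm_b, atac = atac,
              target_peaks = target_peaks, genes = genes, deg = deg,
              params = list(min_support = min_support,
                            promoter_halfwidth = promoter_halfwidth,
                            max_gene_distance = max_gene_distance,
                            scan_threshold = scan_threshold,
                            min_fold = min_fold, max_padj = max_padj,
                            n_shuffles = n_shuffles, min_bp = min_bp,
                            seed = as.integer(seed)))
  available <- .available_stages(cfg)
  if (!is.null(stages)) {
    unknown <- setdiff(stages, names(available))
    if (length(unknown))
      stop("validation error: unknown stage(s): ",
           paste(unknown, collapse = ", "))
    absent <- stages[!unlist(available[stages])]
    if (length(absent))
      stop("validation error: stage(s) requested but inputs missing: ",
           paste(absent, collapse = ", "))
    cfg$stages <- stages
  } else cfg$stages <- names(available)[unlist(available)]
  class(cfg) <- "run_config"
  cfg
}

.available_stages <- function(cfg) {
  has <- function(x) !is.null(cfg[[x]])
  list(consensus = has("replicate_peaks"),
       annotate = has("replicate_peaks") && has("genes"),
       cooccur = has("replicate_peaks") && has("fasta") &&
         has("pwm_a") && has("pwm_b"),
       spacing = has("replicate_peaks") && has("fasta") &&
         has("pwm_a") && has("pwm_b"),
       permtest = has("replicate_peaks") && has("target_peaks") &&
         has("chrom_sizes"),
       accessibility = has("replicate_peaks") && has("atac"),
       degcross = has("replicate_peaks") && has("fasta") &&
         has("pwm_a") && has("pwm_b") && has("genes") && has("deg"))
}

.load_intervals <- function(x, dialect = "bed6") {
  if (is.character(x)) read_bed(x, dialect) else x
}

.load_pwm <- function(x) {
  if (inherits(x, "pwm")) return(x)
  if (grepl("\\.meme$", x, ignore.case = TRUE)) read_meme(x)[[1]]
  else read_jaspar(x)[[1]]
}

#' Run the integrative binding-analysis pipeline
#'
#' Chains the stages enabled by the configuration: consensus peaks ->
#' region annotation and gene assignment -> PWM co-occurrence -> motif
#' spacing -> permutation overlap test -> accessibility partition -> DEG
#' direction crosstab. Writes a versioned JSON report (plus per-stage TSV
#' tables) into `out_dir`; every stage's parameters and the seed are echoed
#' into the report, and identical configurations produce byte-identical
#' reports.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and just returns the report.
#' @return the report, invisibly a list (also serialized as
#'   `report.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  report <- list(schema_version = "1.0", parameters = p,
                 stages = config$stages)
  tsv <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  reps <- lapply(config$replicate_peaks, .load_intervals)
  consensus <- run_stage("consensus",
                         consensus_peaks(reps, p$min_support))
  report$consensus <- list(n_replicates = length(reps),
                           min_support = p$min_support,
                           n_peaks = length(consensus))
  names(consensus) <- sprintf("peak_%04d", seq_along(consensus))
  tsv$consensus_peaks <- data.frame(
    chrom = as.character(seqnames(consensus)),
    start = start(consensus) - 1L, end = end(consensus),
    name = names(consensus), support = consensus$support)

  if ("annotate" %in% config$stages) {
    genes <- if (is.character(config$genes))
      read_gene_models(config$genes) else config$genes
    region <- run_stage("annotate",
                        annotate_region(consensus, genes,
                                        promoter_halfwidth =
                                          p$promoter_halfwidth))
    asg <- assign_to_genes(consensus, genes, p$max_gene_distance)
    report$annotate <- list(
      region_counts = as.list(table(region)),
      n_bound_genes = length(bound_genes(asg)))
    tsv$peak_annotation <- cbind(tsv$consensus_peaks,
                                 region = as.character(region))
    tsv$peak_gene_assignment <- asg
  }

  hits <- NULL
  if (any(c("cooccur", "spacing", "degcross") %in% config$stages)) {
    seqs <- if (is.character(config$fasta))
      readDNAStringSet(config$fasta) else config$fasta
    pa <- .load_pwm(config$pwm_a)
    pb <- .load_pwm(config$pwm_b)
    thr_a <- if (is.null(p$scan_threshold)) 0.9 * max_score(pa) else
      p$scan_threshold
    thr_b <- if (is.null(p$scan_threshold)) 0.9 * max_score(pb) else
      p$scan_threshold
    hits <- run_stage("cooccur", list(
      a = scan_pwm(consensus, seqs, pa, thr_a),
      b = scan_pwm(consensus, seqs, pb, thr_b)))
    cooc <- classify_cooccurrence(consensus, hits$a, hits$b)
    report$cooccur <- list(
      n_a_only = cooc$n_a_only, n_b_only = cooc$n_b_only,
      n_both = cooc$n_both, n_neither = cooc$n_neither,
      total = cooc$total, percent = as.list(cooc$percent))
    spacing <- pair_distance_distribution(consensus, hits$a, hits$b)
    report$spacing <- list(n_pairs = length(spacing$distances),
                           median = spacing$median,
                           modal_bin = as.list(spacing$modal_bin))
    tsv$motif_spacing <- data.frame(distance = spacing$distances)
    report$cooccur_class <- NULL
    cls_per <- cooc$class_per_container
  }

  if ("permtest" %in% config$stages) {
    layout <- if (is.character(config$chrom_sizes))
      read_chrom_sizes(config$chrom_sizes) else config$chrom_sizes
    target <- .load_intervals(config$target_peaks)
    perm <- run_stage("permtest",
                      permutation_overlap_test(consensus, target, layout,
                                               n_shuffles = p$n_shuffles,
                                               seed = p$seed,
                                               min_bp = p$min_bp))
    report$permtest <- list(observed = perm$observed,
                            p.value = perm$p.value,
                            null_mean = mean(perm$null_counts),
                            n_shuffles = perm$n_shuffles,
                            seed = perm$seed)
    tsv$permutation_null <- data.frame(null_count = perm$null_counts)
  }

  if ("accessibility" %in% config$stages) {
    atac <- .load_intervals(config$atac)
    acc <- run_stage("accessibility",
                     classify_accessibility(consensus, atac, p$min_bp))
    report$accessibility <- list(n_accessible = acc$n_accessible,
                                 n_ccr = acc$n_ccr,
                                 ccr_percent = acc$ccr_percent)
    tsv$accessibility <- data.frame(name = names(consensus),
                                    label = as.character(acc$labels))
    if (!is.null(hits)) {
      ct <- tryCatch(
        crosstab_chi2(cls_per, as.character(acc$labels)),
        error = function(e) NULL)
      if (!is.null(ct))
        report$accessibility_by_class <- list(statistic = ct$statistic,
                                              df = ct$df, p.value = ct$p.value)
    }
  }

  if ("degcross" %in% config$stages) {
    deg <- if (is.character(config$deg)) read_deg_table(config$deg) else
      config$deg
    genes <- if (is.character(config$genes))
      read_gene_models(config$genes) else config$genes
    asg <- assign_to_genes(consensus, genes, p$max_gene_distance)
    # gene class = union of its peaks' motif content
    gene_cls <- run_stage("degcross", {
      per_gene <- split(cls_per[asg$peak_id], asg$gene_id)
      vapply(per_gene, function(v) {
        v <- unique(v)
        if ("both" %in% v || all(c("a_only", "b_only") %in% v)) "both"
        else if ("a_only" %in% v) "a_only"
        else if ("b_only" %in% v) "b_only" else "neither"
      }, character(1))
    })
    multi <- vapply(split(cls_per[asg$peak_id], asg$gene_id),
                    function(v) length(unique(v)) > 1, logical(1))
    if (any(multi))
      message(sum(multi), " gene(s) with peaks in multiple motif classes; ",
              "classified by union")
    dbc <- direction_by_class(gene_cls, deg, p$min_fold, p$max_padj)
    report$degcross <- list(
      proportions = dbc$proportions,
      test = if (!is.null(dbc$test))
        list(statistic = dbc$test$statistic, df = dbc$test$df,
             p.value = dbc$test$p.value) else NULL)
    tsv$deg_by_class <- dbc$proportions
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(tsv))
      write.table(tsv[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
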