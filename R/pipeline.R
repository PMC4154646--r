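#' Pipeline configuration
#'
#' Collects every tunable constant of the comparative profiling pipeline.
#' Defaults follow the analysis conventions for human data: effective
#' genome size 2.7e9 bp, 50 gene-body bins plus 50 upstream and 50
#' downstream flank bins of 200 bp, 100 intergenic bins per region, 30 kb
#' minimum upstream gap trimmed by 10 kb at both ends, classification at
#' p < 0.002 with a not-expressed cutoff of 3 log units and a 4-positive
#' probe filter, and a +/- 2 kb promoter window.
#'
#' @param g_eff effective genome size in bp, or `"genome"` to use the
#'   track genome's total length (appropriate for synthetic genomes).
#' @param fragment_length `"estimate"` (strand cross-correlation) or a
#'   fixed length in bp.
#' @param search_range lag range for fragment-length estimation.
#' @param flank,body_bins,flank_bin gene profile layout.
#' @param intergenic_bins bins per intergenic region.
#' @param min_gap,trim intergenic selection rule (`min_gap > 2 * trim`).
#' @param p_threshold,low_expr,min_positive expression classification.
#' @param promoter_window promoter half-width for peak assignment.
#' @param pseudocount ratio-curve pseudocount.
#' @param diag_window diagnostics window size in bp.
#' @param track_kind `"centered"` (default) or `"coverage"` region
#'   densities.
#' @param var_equal pooled-variance Student instead of Welch when `TRUE`.
#' @param seed integer recorded in the run log.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(g_eff = 2.7e9, fragment_length = "estimate",
                            search_range = c(50, 500),
                            flank = 10000, body_bins = 50,
                            flank_bin = 200, intergenic_bins = 100,
                            min_gap = 30000, trim = 10000,
                            p_threshold = 0.002, low_expr = 3,
                            min_positive = 4, promoter_window = 2000,
                            pseudocount = 0.5, diag_window = 10000,
                            track_kind = c("centered", "coverage"),
                            var_equal = FALSE, seed = 1) {
  track_kind <- match.arg(track_kind)
  cfg <- list(g_eff = g_eff, fragment_length = fragment_length,
              search_range = search_range, flank = flank,
              body_bins = body_bins, flank_bin = flank_bin,
              intergenic_bins = intergenic_bins, min_gap = min_gap,
              trim = trim, p_threshold = p_threshold,
              low_expr = low_expr, min_positive = min_positive,
              promoter_window = promoter_window,
              pseudocount = pseudocount, diag_window = diag_window,
              track_kind = track_kind, var_equal = var_equal,
              seed = as.integer(seed))
  if (cfg$min_gap <= 2 * cfg$trim)
    stop("min_gap must exceed 2 * trim")
  counts <- c(cfg$flank, cfg$body_bins, cfg$flank_bin,
              cfg$intergenic_bins, cfg$min_gap, cfg$p_threshold,
              cfg$low_expr, cfg$min_positive, cfg$promoter_window,
              cfg$diag_window)
  if (any(counts <= 0)) stop("pipeline constants must be positive")
  if (!identical(cfg$g_eff, "genome") &&
      (!is.numeric(cfg$g_eff) || cfg$g_eff <= 0))
    stop("g_eff must be positive or \"genome\"")
  structure(cfg, class = "pipeline_config")
}

resolve_g_eff <- function(cfg, genome) {
  if (identical(cfg$g_eff, "genome")) genome_size(genome) else cfg$g_eff
}

# One condition: dedup -> fragment length -> centers/fragments -> track
# -> normalization. Returns the normalized track plus stage metadata.
process_condition <- function(rs, cfg, label, log) {
  log("stage dedup [", label, "]: ", nrow(rs), " reads in")
  rs <- deduplicate(rs)
  log("stage dedup [", label, "]: ", nrow(rs), " reads kept")
  L <- if (identical(cfg$fragment_length, "estimate")) {
    est <- estimate_fragment_length(rs, cfg$search_range)
    log("stage fraglen [", label, "]: estimated ", est$length, " bp")
    est$length
  } else {
    log("stage fraglen [", label, "]: fixed at ", cfg$fragment_length,
        " bp")
    as.integer(cfg$fragment_length)
  }
  tr <- if (cfg$track_kind == "centered")
    centered_counts(shift_to_centers(rs, L), rs_genome(rs))
  else
    fragment_coverage(extend_to_fragments(rs, L), rs_genome(rs))
  g_eff <- resolve_g_eff(cfg, rs_genome(rs))
  nt <- normalize_track(tr, n_reads = nrow(rs), g_eff = g_eff)
  log("stage normalize [", label, "]: n_reads = ", nrow(rs),
      ", g_eff = ", format(g_eff, scientific = FALSE))
  list(track = nt, n_reads = nrow(rs), fragment_length = L)
}

#' Run the comparative profiling pipeline end to end
#'
#' Executes, for each condition: duplicate removal, fragment-length
#' estimation, read shifting (or extension), track building and
#' effective-genome-size normalization; then gene and intergenic
#' profiling, expression classification, per-class condition-ratio
#' curves and the log-ratio bimodality diagnostic. Every result table is
#' written as TSV to `output_dir` together with a manifest and a log of
#' all resolved parameters; reruns with identical inputs are
#' byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param reads_a,reads_b [read_set()]s (or BED paths) for condition A
#'   (numerator, e.g. MMSET-high) and condition B.
#' @param expression a gene-level [expression_matrix()] (or TSV path from
#'   [write_expression_tsv()]).
#' @param ann an [annotation()] (or TSV path).
#' @param genome a [genome()]; required when any input is given as a
#'   path.
#' @param output_dir directory for result files; created if missing.
#' @return (invisibly) list with `tracks`, `gene_profiles`,
#'   `intergenic_profiles`, `regions`, `classes`, `ratio_curves`,
#'   `diagnostics`, `fragment_lengths`, `manifest`.
#' @export
run_pipeline <- function(cfg, reads_a, reads_b, expression, ann,
                         genome = NULL, output_dir = tempfile("mmrun")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(ann)) ann <- read_annotation_table(ann, genome)
  genome <- ann_genome(ann)
  if (is.character(reads_a)) reads_a <- read_reads_bed(reads_a, genome)
  if (is.character(reads_b)) reads_b <- read_reads_bed(reads_b, genome)
  if (is.character(expression))
    expression <- read_expression_tsv(expression)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log <- function(...) writeLines(paste0(...), log_con)
  log("pipeline_config: ",
      paste(names(unclass(cfg)),
            vapply(unclass(cfg), function(v)
              paste(format(v, scientific = FALSE), collapse = ","),
              character(1)),
            sep = "=", collapse = "; "))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  condA <- run_stage("tracks[A]",
                     process_condition(reads_a, cfg, "A", log))
  condB <- run_stage("tracks[B]",
                     process_condition(reads_b, cfg, "B", log))

  regions <- run_stage("intergenic", select_intergenic_regions(
    ann, min_gap = cfg$min_gap, trim = cfg$trim))
  log("stage intergenic: ", nrow(regions), " regions selected")

  profA <- run_stage("profiles[A]", profile_genes(
    condA$track, ann, cfg$flank, cfg$body_bins, cfg$flank_bin))
  profB <- run_stage("profiles[B]", profile_genes(
    condB$track, ann, cfg$flank, cfg$body_bins, cfg$flank_bin))
  intA <- run_stage("intergenic_profiles[A]", profile_intergenic_regions(
    condA$track, regions, cfg$intergenic_bins))
  intB <- run_stage("intergenic_profiles[B]", profile_intergenic_regions(
    condB$track, regions, cfg$intergenic_bins))

  classes <- run_stage("classify", classify_genes(
    expression, p_threshold = cfg$p_threshold, low_expr = cfg$low_expr,
    var_equal = cfg$var_equal))
  log("stage classify: ",
      paste(names(table(classes$class)), table(classes$class),
            sep = "=", collapse = ", "))

  curves <- run_stage("ratios", class_ratio_profile(
    profA, profB, classes, pseudocount = cfg$pseudocount))

  diag <- run_stage("diagnose", {
    lr <- window_log_ratios(condA$track, condB$track,
                            window = cfg$diag_window)
    list(log_ratios = lr, report = assess_bimodality(lr))
  })
  log("stage diagnose: b = ", format(diag$report$coefficient),
      " (", diag$report$verdict, "), norm_factor = ",
      format(attr(diag$log_ratios, "norm_factor")))

  files <- c(gene_profiles_A = "gene_profiles_A.tsv",
             gene_profiles_B = "gene_profiles_B.tsv",
             intergenic_profiles_A = "intergenic_profiles_A.tsv",
             intergenic_profiles_B = "intergenic_profiles_B.tsv",
             gene_classes = "gene_classes.tsv",
             ratio_curves = "ratio_curves.tsv",
             log_ratios = "log_ratios.tsv",
             diagnostics = "diagnostics.txt")
  write_profile_matrix(profA, file.path(output_dir, files[1]))
  write_profile_matrix(profB, file.path(output_dir, files[2]))
  write_profile_matrix(intA, file.path(output_dir, files[3]))
  write_profile_matrix(intB, file.path(output_dir, files[4]))
  write_class_table(classes, file.path(output_dir, files[5]))
  curve_df <- data.frame(class = names(curves),
                         do.call(rbind, lapply(curves, rbind)))
  colnames(curve_df) <- c("class", paste0("bin_", seq_len(ncol(profA))))
  write.table(curve_df, file.path(output_dir, files[6]), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(diag$log_ratios),
              file.path(output_dir, files[7]), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c(paste0("bimodality_coefficient\t",
                      format(diag$report$coefficient)),
               paste0("verdict\t", diag$report$verdict),
               paste0("threshold\t", diag$report$threshold),
               paste0("norm_factor\t",
                      format(attr(diag$log_ratios, "norm_factor"))),
               paste0("window\t", cfg$diag_window)),
             file.path(output_dir, files[8]))
  manifest <- data.frame(key = names(files), file = unname(files))
  write.table(manifest, file.path(output_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log("pipeline complete: ", length(files), " result files")

  invisible(list(
    tracks = list(a = condA$track, b = condB$track),
    fragment_lengths = c(a = condA$fragment_length,
                         b = condB$fragment_length),
    gene_profiles = list(a = profA, b = profB),
    intergenic_profiles = list(a = intA, b = intB),
    regions = regions, classes = classes, ratio_curves = curves,
    diagnostics = diag, manifest = manifest, output_dir = output_dir))
}
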