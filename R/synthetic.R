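#' Configuration for the synthetic ChIP-seq experiment generator
#'
#' Bundles the study conditions the generator emulates: a "focal" regime
#' with TSS-proximal enrichment over expressed genes on a low uniform
#' background (the MMSET-low / TKO-like pattern) and a "diffuse" regime
#' whose signal is uniform, boundary-less and globally elevated
#' `diffuse_fold`-fold in total mass (the MMSET-high / NTKO-like pattern,
#' default 8-fold), plus a 6+6-replicate log-scale expression matrix with
#' planted up-, down- and not-expressed genes.
#'
#' @param chromosomes named chromosome lengths in bp.
#' @param n_genes number of genes to place.
#' @param gene_length_range `(min, max)` gene length in bp.
#' @param gap_mixture fraction of intergenic gaps drawn at 45 kb (above
#'   the 30 kb intergenic-selection rule); the rest are 15 kb. A two-point
#'   mixture keeps the rule's truth set crisp.
#' @param fragment_length true fragment length in bp.
#' @param n_fragments fragments per condition (focal condition; the
#'   diffuse condition draws `diffuse_fold` times the focal background
#'   mass).
#' @param focal_peak_height TSS enrichment of expressed genes over the
#'   uniform background in the focal condition (fold over background at
#'   the peak mode).
#' @param focal_peak_sd sd (bp) of the Gaussian TSS component.
#' @param diffuse_fold total-mass multiplier of the diffuse condition
#'   (default 8).
#' @param n_replicates expression replicates per condition (default 6).
#' @param effect_size_up,effect_size_down planted log-scale shifts of
#'   condition A for up-/down-regulated genes.
#' @param noise_sd log-scale expression noise sd.
#' @param baseline_expr log-scale mean of expressed genes.
#' @param notexpr_baseline log-scale mean of not-expressed genes (< 3).
#' @param class_fractions named fractions for `up`, `down`, `no_change`,
#'   `not_expressed` (must sum to 1).
#' @param seed integer seed; every generator derives its stream from it.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(chromosomes = c(chr1 = 1.6e6, chr2 = 1.2e6),
                       n_genes = 60,
                       gene_length_range = c(5000, 15000),
                       gap_mixture = 0.5,
                       fragment_length = 150,
                       n_fragments = 2e5,
                       focal_peak_height = 10,
                       focal_peak_sd = 1000,
                       diffuse_fold = 8,
                       n_replicates = 6,
                       effect_size_up = 2,
                       effect_size_down = 2,
                       noise_sd = 0.5,
                       baseline_expr = 6,
                       notexpr_baseline = 2,
                       class_fractions = c(up = 0.15, down = 0.10,
                                           no_change = 0.60,
                                           not_expressed = 0.15),
                       seed = 42) {
  cfg <- list(chromosomes = unclass(check_genome(chromosomes)),
              n_genes = n_genes, gene_length_range = gene_length_range,
              gap_mixture = gap_mixture,
              fragment_length = fragment_length,
              n_fragments = n_fragments,
              focal_peak_height = focal_peak_height,
              focal_peak_sd = focal_peak_sd, diffuse_fold = diffuse_fold,
              n_replicates = n_replicates,
              effect_size_up = effect_size_up,
              effect_size_down = effect_size_down, noise_sd = noise_sd,
              baseline_expr = baseline_expr,
              notexpr_baseline = notexpr_baseline,
              class_fractions = class_fractions, seed = as.integer(seed))
  if (cfg$fragment_length < 1 ||
      cfg$fragment_length >= min(cfg$chromosomes))
    stop("fragment_length must be >= 1 and < the shortest chromosome")
  if (cfg$n_replicates < 2) stop("n_replicates must be >= 2")
  if (cfg$gap_mixture < 0 || cfg$gap_mixture > 1)
    stop("gap_mixture must lie in [0, 1]")
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8 ||
      !all(c("up", "down", "no_change", "not_expressed") %in%
           names(cfg$class_fractions)))
    stop("class_fractions must name the four classes and sum to 1")
  if (cfg$notexpr_baseline >= 3)
    stop("notexpr_baseline must be < 3 (the not-expressed cutoff)")
  if (cfg$seed + 10 > .Machine$integer.max)
    stop("seed too large")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes on ",
      format(sum(x$chromosomes), big.mark = ","), " bp; L* = ",
      x$fragment_length, " bp; ", format(x$n_fragments, big.mark = ","),
      " focal fragments; diffuse fold ", x$diffuse_fold, "; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

sim_genome <- function(cfg) genome(cfg$chromosomes)

# Gap draw: 45 kb with probability gap_mixture, else 15 kb.
draw_gaps <- function(n, gap_mixture) {
  ifelse(runif(n) < gap_mixture, 45000, 15000)
}

#' Generate a non-overlapping strand-randomized gene annotation
#'
#' Genes are distributed over chromosomes proportionally to length and
#' laid down left to right, each preceded by an intergenic gap drawn from
#' the two-point 15 kb / 45 kb mixture, with uniform lengths and uniform
#' random strands. Deterministic under a fixed config seed.
#'
#' @param cfg a [sim_config()].
#' @return an [annotation()].
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- sim_genome(cfg)
  lens <- cfg$chromosomes
  per_chrom <- round(cfg$n_genes * lens / sum(lens))
  d <- cfg$n_genes - sum(per_chrom)
  per_chrom[1] <- per_chrom[1] + d
  rows <- list()
  for (cn in names(lens)) {
    n <- per_chrom[[cn]]
    if (n == 0) next
    gaps <- draw_gaps(n, cfg$gap_mixture)
    if (cfg$gap_mixture > 0 && cfg$gap_mixture < 1 && n >= 2) {
      if (!any(gaps >= 30000)) gaps[1] <- 45000
      if (!any(gaps < 30000)) gaps[1] <- 15000
    }
    glen <- round(runif(n, cfg$gene_length_range[1],
                        cfg$gene_length_range[2]))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    cursor <- 0
    for (j in seq_len(n)) {
      s <- cursor + gaps[j]
      e <- s + glen[j]
      if (e > lens[[cn]])
        stop("genome too small for ", cfg$n_genes, " genes: chromosome ",
             cn, " overflows at gene ", j)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = sprintf("%s_g%03d", cn, j), chrom = cn,
        strand = strands[j], tx_start = s, tx_end = e,
        stringsAsFactors = FALSE)
      cursor <- e
    }
  }
  df <- do.call(rbind, rows)
  annotation(df$gene_id, df$chrom, df$strand, df$tx_start, df$tx_end, g)
}

#' Plant ground-truth gene classes and enrichment expectations
#'
#' Assigns every gene one of the four expression classes according to
#' `class_fractions` (counts rounded, remainder to `no_change`), records
#' the expected focal TSS enrichment (`focal_peak_height` for expressed
#' genes, 0 for `not_expressed`), the true fragment length, and the
#' brute-force list of strand-oriented upstream gaps of at least 30 kb
#' (the oracle intergenic set).
#'
#' @param cfg a [sim_config()].
#' @param ann the [generate_annotation()] output.
#' @return list of class `"sim_truth"` with `classes` (named character),
#'   `tss_enrichment` (named numeric), `fragment_length`, `oracle_gaps`
#'   (`data.frame` chrom/start/end/gene_id).
#' @export
simulate_truth <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "annotation"))
  set.seed(cfg$seed + 1L)
  n <- nrow(ann)
  counts <- round(cfg$class_fractions * n)
  counts["no_change"] <- n - sum(counts[names(counts) != "no_change"])
  labels <- rep(names(counts), counts)
  classes <- setNames(sample(labels), ann$gene_id)
  enr <- setNames(ifelse(classes == "not_expressed", 0,
                         cfg$focal_peak_height), names(classes))
  g <- unclass(ann_genome(ann))
  gaps <- list()
  for (i in seq_len(nrow(ann))) {
    gene <- ann[i, ]
    others <- ann[ann$chrom == gene$chrom &
                  ann$gene_id != gene$gene_id, ]
    if (gene$strand == "+") {
      cand <- others$tx_end[others$tx_end <= gene$tx_start]
      lo <- if (length(cand)) max(cand) else 0
      hi <- gene$tx_start
    } else {
      cand <- others$tx_start[others$tx_start >= gene$tx_end]
      lo <- gene$tx_end
      hi <- if (length(cand)) min(cand) else g[[gene$chrom]]
    }
    if (hi - lo >= 30000)
      gaps[[length(gaps) + 1]] <- data.frame(
        chrom = gene$chrom, start = lo, end = hi, gene_id = gene$gene_id,
        stringsAsFactors = FALSE)
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps)
          else data.frame(chrom = character(), start = numeric(),
                          end = numeric(), gene_id = character())
  structure(list(classes = classes, tss_enrichment = enr,
                 fragment_length = cfg$fragment_length,
                 oracle_gaps = gaps),
            class = "sim_truth")
}

#' Gene ids planted as expressed in a simulation truth
#' @param truth a [simulate_truth()] result.
#' @return character vector of expressed (not `not_expressed`) gene ids.
#' @export
expressed_genes <- function(truth) {
  names(truth$classes)[truth$classes != "not_expressed"]
}

#' Sample single-end reads from a fragment-midpoint mixture density
#'
#' Fragment midpoints are drawn from a weighted mixture of components;
#' each fragment `[m - floor(L/2), m - floor(L/2) + L)` emits one read
#' from a uniformly chosen end: a '+' read at the fragment start or a '-'
#' read at its last base. Read positions are clipped to chromosome
#' bounds. This is the primitive behind [generate_reads()]; custom
#' component tables let tests plant arbitrary enrichment structure.
#'
#' @param genome a [genome()].
#' @param n_fragments number of fragments (one read each).
#' @param fragment_length fragment length L in bp.
#' @param components `data.frame` with columns `type` (`"uniform"`
#'   genome-wide; `"gaussian"` with `chrom`, `p1` = mean, `p2` = sd;
#'   `"interval"` with `chrom`, `p1` = start, `p2` = end, uniform),
#'   `chrom`, `p1`, `p2` and `weight` (relative fragment mass).
#' @param seed optional integer seed.
#' @return a [read_set()].
#' @export
sample_fragment_reads <- function(genome, n_fragments, fragment_length,
                                  components, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- check_genome(genome)
  lens <- unclass(genome)
  w <- components$weight / sum(components$weight)
  comp <- sample.int(nrow(components), n_fragments, replace = TRUE,
                     prob = w)
  chrom <- character(n_fragments)
  mid <- numeric(n_fragments)
  for (i in seq_len(nrow(components))) {
    sel <- comp == i
    k <- sum(sel)
    if (k == 0) next
    row <- components[i, ]
    if (row$type == "uniform") {
      cn <- sample(names(lens), k, replace = TRUE, prob = lens)
      chrom[sel] <- cn
      mid[sel] <- floor(runif(k) * lens[cn])
    } else if (row$type == "gaussian") {
      chrom[sel] <- row$chrom
      mid[sel] <- round(rnorm(k, row$p1, row$p2))
    } else if (row$type == "interval") {
      chrom[sel] <- row$chrom
      mid[sel] <- floor(runif(k, row$p1, row$p2))
    } else stop("unknown component type: ", row$type)
  }
  mid <- pmax(0, pmin(mid, lens[chrom] - 1))
  half <- floor(fragment_length / 2)
  s <- mid - half
  strand <- sample(c("+", "-"), n_fragments, replace = TRUE)
  pos <- ifelse(strand == "+", s, s + fragment_length - 1)
  pos <- pmax(0, pmin(pos, lens[chrom] - 1))
  read_set(chrom, pos, strand, genome)
}

#' Simulate reads piled on discrete binding sites
#'
#' Draws `n_sites` site positions uniformly over the genome and places
#' every fragment midpoint exactly on a site (uniformly chosen), so the
#' Watson and Crick 5'-read frequency vectors are point sources separated
#' by exactly `fragment_length - 1` bp. This punctate structure is what
#' makes the strand cross-correlation peak unambiguous; broad domain-like
#' enrichment (the focal Gaussian regime) smears it, as it does in real
#' histone-mark data.
#'
#' @param genome a [genome()].
#' @param n_fragments number of fragments.
#' @param fragment_length true fragment length in bp.
#' @param n_sites number of binding sites (default 200).
#' @param seed optional integer seed.
#' @return a [read_set()].
#' @export
simulate_binding_site_reads <- function(genome, n_fragments,
                                        fragment_length, n_sites = 200,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- check_genome(genome)
  lens <- unclass(genome)
  cn <- sample(names(lens), n_sites, replace = TRUE, prob = lens)
  # keep whole fragments clear of chromosome ends
  pos <- floor(runif(n_sites, fragment_length,
                     lens[cn] - fragment_length))
  comp <- data.frame(type = "gaussian", chrom = cn, p1 = pos, p2 = 0,
                     weight = 1, stringsAsFactors = FALSE)
  sample_fragment_reads(genome, n_fragments, fragment_length, comp)
}

focal_background_fraction <- function(cfg, n_expressed) {
  G <- sum(cfg$chromosomes)
  1 / (1 + n_expressed * cfg$focal_peak_height * cfg$focal_peak_sd *
         sqrt(2 * pi) / G)
}

#' Simulate reads for the focal or diffuse condition
#'
#' The focal condition draws exactly `n_fragments` fragments from a
#' mixture of a genome-wide uniform background and one Gaussian component
#' (sd `focal_peak_sd`) centred at the TSS of every expressed gene, with
#' each component's mass set so that the midpoint density at a TSS is
#' `focal_peak_height`-fold the background density. The diffuse condition
#' is purely uniform with total mass `diffuse_fold` times the focal
#' background mass, so its per-bp read density in gene-poor windows is
#' `diffuse_fold` times the focal background density. One read per
#' fragment is emitted from a uniformly chosen fragment end.
#'
#' @param ann an [annotation()].
#' @param condition `"focal"` or `"diffuse"`.
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result; when `NULL` all genes count
#'   as expressed.
#' @return a [read_set()].
#' @export
generate_reads <- function(ann, condition, cfg, truth = NULL) {
  stopifnot(inherits(ann, "annotation"), inherits(cfg, "sim_config"))
  if (!condition %in% c("focal", "diffuse"))
    stop("unknown condition '", condition, "' (use 'focal' or 'diffuse')")
  expr_ids <- if (is.null(truth)) ann$gene_id else expressed_genes(truth)
  expr_ids <- intersect(expr_ids, ann$gene_id)
  w_bg <- focal_background_fraction(cfg, length(expr_ids))
  g <- ann_genome(ann)
  if (condition == "focal") {
    t <- tss(ann)[expr_ids]
    comp <- rbind(
      data.frame(type = "uniform", chrom = NA_character_, p1 = NA_real_,
                 p2 = NA_real_, weight = w_bg, stringsAsFactors = FALSE),
      data.frame(type = "gaussian", chrom = ann$chrom[match(expr_ids,
                 ann$gene_id)], p1 = unname(t), p2 = cfg$focal_peak_sd,
                 weight = (1 - w_bg) / length(expr_ids),
                 stringsAsFactors = FALSE))
    sample_fragment_reads(g, cfg$n_fragments, cfg$fragment_length, comp,
                          seed = cfg$seed + 2L)
  } else {
    n_d <- round(cfg$diffuse_fold * w_bg * cfg$n_fragments)
    comp <- data.frame(type = "uniform", chrom = NA_character_,
                       p1 = NA_real_, p2 = NA_real_, weight = 1,
                       stringsAsFactors = FALSE)
    sample_fragment_reads(g, n_d, cfg$fragment_length, comp,
                          seed = cfg$seed + 3L)
  }
}

#' Simulate a replicated log-scale expression matrix with planted classes
#'
#' Expressed genes sit at `baseline_expr`; planted `up` genes are shifted
#' `+effect_size_up` and `down` genes `-effect_size_down` in condition A;
#' `not_expressed` genes sit at `notexpr_baseline` (< 3) in both
#' conditions. Gaussian noise of sd `noise_sd` is added throughout.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @return an [expression_matrix()] (genes x `2 * n_replicates`), columns
#'   `A_1..A_n, B_1..B_n`.
#' @export
generate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(cfg$seed + 4L)
  ids <- names(truth$classes)
  nr <- cfg$n_replicates
  base <- ifelse(truth$classes == "not_expressed", cfg$notexpr_baseline,
                 cfg$baseline_expr)
  mu_a <- base + ifelse(truth$classes == "up", cfg$effect_size_up,
                 ifelse(truth$classes == "down", -cfg$effect_size_down, 0))
  vals <- cbind(
    matrix(rnorm(length(ids) * nr, mu_a, cfg$noise_sd), ncol = nr),
    matrix(rnorm(length(ids) * nr, base, cfg$noise_sd), ncol = nr))
  rownames(vals) <- ids
  colnames(vals) <- c(paste0("A_", seq_len(nr)), paste0("B_", seq_len(nr)))
  expression_matrix(vals, rep(c("A", "B"), each = nr))
}

#' Simulate two peak sets with a controlled promoter-overlap structure
#'
#' Draws `nA_only + n_common + nB_only` distinct genes and places one peak
#' over the promoter (centred at the TSS) of each: A-only genes get a peak
#' in set A, B-only in set B, common genes in both. Common peaks in set A
#' are drawn `height_ratio` times taller and `width_ratio` times wider
#' than their set-B counterparts, emulating shared repressive-complex
#' peaks that grow under the MMSET-high condition.
#'
#' @param cfg a [sim_config()].
#' @param ann an [annotation()].
#' @param overlap_spec integer `(nA_only, n_common, nB_only)`.
#' @param base_height mean height of set-B peaks (arbitrary units).
#' @param base_width set-B peak width in bp.
#' @param height_ratio,width_ratio multipliers for common peaks in set A.
#' @return list with elements `a` and `b` ([peak_set()]s) and
#'   `gene_sets` (list `a_only`, `common`, `b_only` of gene ids).
#' @export
generate_peaks <- function(cfg, ann, overlap_spec,
                           base_height = 10, base_width = 1000,
                           height_ratio = 2, width_ratio = 1.5) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "annotation"),
            length(overlap_spec) == 3)
  total <- sum(overlap_spec)
  if (total > nrow(ann))
    stop("overlap_spec requests ", total, " genes but only ", nrow(ann),
         " are annotated")
  set.seed(cfg$seed + 5L)
  ids <- sample(ann$gene_id, total)
  a_only <- ids[seq_len(overlap_spec[1])]
  common <- ids[overlap_spec[1] + seq_len(overlap_spec[2])]
  b_only <- ids[overlap_spec[1] + overlap_spec[2] +
                seq_len(overlap_spec[3])]
  t <- tss(ann)
  lens <- unclass(ann_genome(ann))
  mk <- function(gene_ids, widths, heights) {
    if (length(gene_ids) == 0)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), height = numeric()))
    cn <- ann$chrom[match(gene_ids, ann$gene_id)]
    ctr <- t[gene_ids]
    data.frame(chrom = cn,
               start = pmax(0, round(ctr - widths / 2)),
               end = pmin(lens[cn], round(ctr + widths / 2)),
               height = heights, stringsAsFactors = FALSE)
  }
  rwidth <- function(n) pmax(200, rnorm(n, base_width, base_width / 8))
  h_common_b <- abs(rnorm(length(common), base_height, base_height / 6))
  w_common_b <- rwidth(length(common))
  pa <- rbind(
    mk(a_only, rwidth(length(a_only)),
       abs(rnorm(length(a_only), base_height, base_height / 6))),
    mk(common, w_common_b * width_ratio, h_common_b * height_ratio))
  pb <- rbind(
    mk(common, w_common_b, h_common_b),
    mk(b_only, rwidth(length(b_only)),
       abs(rnorm(length(b_only), base_height, base_height / 6))))
  list(a = peak_set(pa$chrom, pa$start, pa$end, pa$height,
                    genome = ann_genome(ann)),
       b = peak_set(pb$chrom, pb$start, pb$end, pb$height,
                    genome = ann_genome(ann)),
       gene_sets = list(a_only = a_only, common = common,
                        b_only = b_only))
}

#' Simulate a complete two-condition experiment
#'
#' Convenience wrapper chaining [generate_annotation()],
#' [simulate_truth()], [generate_reads()] for both regimes (condition A =
#' diffuse / MMSET-high, condition B = focal / MMSET-low) and
#' [generate_expression()].
#'
#' @param cfg a [sim_config()].
#' @return list with `cfg`, `annotation`, `truth`, `reads_a` (diffuse),
#'   `reads_b` (focal), `expression`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(cfg, ann)
  list(cfg = cfg, annotation = ann, truth = truth,
       reads_a = generate_reads(ann, "diffuse", cfg, truth),
       reads_b = generate_reads(ann, "focal", cfg, truth),
       expression = generate_expression(cfg, truth))
}
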