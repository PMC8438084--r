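#' Construct a peak set
#'
#' A peak set is a tibble of 0-based half-open intervals `[start, end)` with
#' `tf_name`/`cell_line` metadata attached as attributes. Overlapping or
#' book-ended intervals are merged and the result is sorted, so interval sets
#' are always in canonical form.
#'
#' @param chrom,start,end Interval vectors (BED convention: 0-based half-open).
#' @param tf_name,cell_line Metadata strings.
#' @param score Optional numeric score vector (dropped by merging).
#' @return A `tf_peaks` tibble with columns `chrom`, `start`, `end`.
#' @export
peak_set <- function(chrom, start, end, tf_name = NA_character_,
                     cell_line = NA_character_, score = NULL) {
  if (length(start) && any(start >= end)) {
    abort(sprintf("Interval with start >= end at row(s) %s.",
                  paste(head(which(start >= end), 5), collapse = ", ")))
  }
  tab <- tibble(chrom = as.character(chrom),
                start = as.numeric(start), end = as.numeric(end))
  if (nrow(tab)) {
    gr <- GenomicRanges::reduce(peaks_to_granges(tab))
    tab <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1,
                  end = as.numeric(GenomicRanges::end(gr)))
    tab <- arrange(tab, .data$chrom, .data$start)
  }
  structure(tab, tf_name = tf_name, cell_line = cell_line,
            class = c("tf_peaks", class(tab)))
}

# 0-based half-open [start,end) -> 1-based closed [start+1, end]
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

variants_to_granges <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(start = variants$pos, width = 1))
}

#' Read a BED or narrowPeak file into a peak set
#'
#' Accepts BED3+ or ENCODE 10-column narrowPeak; only the first three columns
#' are used. Chromosome naming is preserved verbatim. Overlapping intervals
#' are merged on load.
#'
#' @param path File path.
#' @param tf_name,cell_line Metadata attached to the peak set.
#' @return A `tf_peaks` tibble (empty with a warning for an empty file).
#' @export
read_peaks <- function(path, tf_name = NA_character_, cell_line = NA_character_) {
  raw <- tryCatch(
    readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                    progress = FALSE, comment = "#"),
    error = function(e) tibble())
  if (!nrow(raw)) {
    warn(sprintf("Empty peak file: %s", path))
    return(peak_set(character(), numeric(), numeric(),
                    tf_name = tf_name, cell_line = cell_line))
  }
  if (ncol(raw) < 3) abort("Peak file must have at least 3 columns (BED3).")
  start <- as.numeric(raw[[2]]); end <- as.numeric(raw[[3]])
  if (any(start >= end)) {
    abort(sprintf("start >= end at data row(s) %s of %s.",
                  paste(head(which(start >= end), 5), collapse = ", "), path))
  }
  peak_set(as.character(raw[[1]]), start, end,
           tf_name = tf_name, cell_line = cell_line)
}

#' Binary TF-binding annotation of variants
#'
#' Builds the variants-by-TFs binary matrix: entry 1 when the variant's
#' (1-based) position falls inside any merged peak of that set, using the BED
#' half-open convention, 0 otherwise. A variant covered by several peaks of
#' the same TF still scores 1 (binding status, not count).
#'
#' @param variants Variant tibble with `chrom` and `pos`.
#' @param peaks A single `tf_peaks` object or a (optionally named) list of
#'   them; unnamed entries are labelled by their `tf_name` attribute.
#' @return A tibble with one 0/1 integer column per peak set, rows aligned to
#'   `variants`, with a `feature_kind` attribute of `"tf"` per column.
#' @export
annotate_tf_binding <- function(variants, peaks) {
  if (inherits(peaks, "tf_peaks")) peaks <- list(peaks)
  if (!length(peaks)) abort("At least one peak set is required.")
  nms <- names(peaks)
  if (is.null(nms)) nms <- rep("", length(peaks))
  auto <- purrr::map_chr(peaks, ~ attr(.x, "tf_name") %||% NA_character_)
  nms <- ifelse(nms == "" | is.na(nms),
                ifelse(is.na(auto), paste0("tf", seq_along(peaks)), auto), nms)
  vgr <- variants_to_granges(variants)
  cols <- purrr::map(peaks, function(p) {
    if (!nrow(p)) return(integer(nrow(variants)))
    as.integer(IRanges::overlapsAny(vgr, peaks_to_granges(p)))
  })
  out <- as_tibble(setNames(cols, make.unique(nms)))
  structure(out, feature_kind = setNames(rep("tf", ncol(out)), names(out)))
}

#' Per-variant TF-occupancy score and categories
#'
#' The TF score of a variant is the number of distinct TFs (from a chosen
#' panel) whose binding sites cover it. Scores are bucketed into ordered
#' categories; with the default cut points the buckets are `0`, `1-5` and
#' `6-<max>`, the stratification used for chromatin-interaction models.
#'
#' @param annotation A binary annotation tibble from [annotate_tf_binding()].
#' @param tf_subset Character vector of column names to sum over (default all
#'   `tf`-kind columns).
#' @param cuts Integer upper bounds of all but the last category
#'   (default `c(0, 5)`).
#' @return A tibble with integer `score` and ordered factor `category`.
#' @export
compute_tf_score <- function(annotation, tf_subset = NULL, cuts = c(0, 5)) {
  kind <- attr(annotation, "feature_kind")
  tf_cols <- if (!is.null(kind)) names(kind)[kind == "tf"] else names(annotation)
  if (is.null(tf_subset)) tf_subset <- tf_cols
  missing_tf <- setdiff(tf_subset, names(annotation))
  if (length(missing_tf)) {
    abort(sprintf("Unknown TF column(s): %s", paste(missing_tf, collapse = ", ")))
  }
  score <- as.integer(rowSums(as.matrix(annotation[, tf_subset, drop = FALSE])))
  n_tf <- length(tf_subset)
  cuts <- sort(unique(as.integer(cuts)))
  cuts <- cuts[cuts < n_tf] # cut points at/above the panel size are vacuous
  lower <- c(0L, cuts + 1L)
  upper <- c(cuts, n_tf)
  labs <- ifelse(lower == upper, as.character(lower), paste0(lower, "-", upper))
  category <- cut(score, breaks = c(-1L, upper), labels = labs, ordered_result = TRUE)
  tibble(score = score, category = category)
}

#' Chromatin-state annotation of variants
#'
#' Assigns each variant the ChromHMM-style state of the segment covering it.
#' The segmentation must be non-overlapping; variants outside any segment get
#' the configured background state with a logged count.
#'
#' @param variants Variant tibble with `chrom` and `pos`.
#' @param segmentation Tibble with `chrom`, `start`, `end` (BED, 0-based
#'   half-open) and `state` (mnemonic), e.g. from [read_chromhmm()].
#' @param background_state Label for unsegmented positions (default "Quies").
#' @return A tibble with a `state` factor column plus one 0/1 dummy column per
#'   observed state (`feature_kind` attribute `"chromatin_state"`); the
#'   dummies are mutually exclusive and exhaustive.
#' @export
annotate_chromatin <- function(variants, segmentation, background_state = "Quies") {
  seg_gr <- peaks_to_granges(segmentation)
  ov <- GenomicRanges::findOverlaps(seg_gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov)) {
    bad <- unique(c(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov)))
    abort(sprintf("Overlapping segmentation rows: %s",
                  paste(head(sort(bad), 10), collapse = ", ")))
  }
  vgr <- variants_to_granges(variants)
  hit <- GenomicRanges::findOverlaps(vgr, seg_gr, select = "first")
  state <- ifelse(is.na(hit), background_state, segmentation$state[hit])
  n_out <- sum(is.na(hit))
  if (n_out > 0) {
    warn(sprintf("%d variant(s) outside the segmentation assigned background state '%s'.",
                 n_out, background_state))
  }
  levs <- sort(unique(c(state, background_state)))
  state <- factor(state, levels = levs)
  dummies <- as_tibble(setNames(
    purrr::map(levs, ~ as.integer(state == .x)), paste0("state_", levs)))
  out <- dplyr::bind_cols(tibble(state = state), dummies)
  structure(out, feature_kind = setNames(
    rep("chromatin_state", length(levs)), paste0("state_", levs)))
}

#' Read a ChromHMM dense segmentation BED
#'
#' @param path BED file with the state mnemonic in column 4.
#' @return Tibble with `chrom`, `start`, `end`, `state`.
#' @export
read_chromhmm <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(raw) < 4) abort("ChromHMM BED must have >= 4 columns (state in column 4).")
  tibble(chrom = as.character(raw[[1]]), start = as.numeric(raw[[2]]),
         end = as.numeric(raw[[3]]), state = as.character(raw[[4]]))
}

#' Motif-status strata for variants inside a TF's peaks
#'
#' Variants inside the TF's binding sites are stratified by whether they also
#' fall in a hit of the TF's own (host) motif, a different known motif, or no
#' known motif. Host status takes precedence when both hit sets cover a
#' variant. Variants outside the peaks carry `NA`.
#'
#' @param variants Variant tibble.
#' @param host_motif_hits,other_motif_hits Interval tibbles (`chrom`, `start`,
#'   `end`; BED convention), e.g. from [read_peaks()]; may be empty.
#' @param tf_peaks A `tf_peaks` object for the TF of interest.
#' @return Tibble with a `motif_status` factor (`host`, `non_host`, `none`;
#'   `NA` outside peaks) and matching dummy columns
#'   (`feature_kind` = `"motif_stratum"`).
#' @export
annotate_motif_strata <- function(variants, host_motif_hits, other_motif_hits,
                                  tf_peaks) {
  vgr <- variants_to_granges(variants)
  in_peak <- IRanges::overlapsAny(vgr, peaks_to_granges(tf_peaks))
  in_host <- if (nrow(host_motif_hits)) {
    IRanges::overlapsAny(vgr, peaks_to_granges(host_motif_hits))
  } else rep(FALSE, nrow(variants))
  in_other <- if (nrow(other_motif_hits)) {
    IRanges::overlapsAny(vgr, peaks_to_granges(other_motif_hits))
  } else rep(FALSE, nrow(variants))
  status <- rep(NA_character_, nrow(variants))
  status[in_peak] <- "none"
  status[in_peak & in_other] <- "non_host"
  status[in_peak & in_host] <- "host" # host wins ties
  status <- factor(status, levels = c("host", "non_host", "none"))
  dummies <- as_tibble(setNames(
    purrr::map(levels(status), ~ as.integer(!is.na(status) & status == .x)),
    paste0("motif_", levels(status))))
  out <- dplyr::bind_cols(tibble(motif_status = status), dummies)
  structure(out, feature_kind = setNames(
    rep("motif_stratum", 3), paste0("motif_", levels(status))))
}

#' Enrichment of TF binding near GWAS hits
#'
#' Compares the frequency of TF binding within `window` bp of GWAS-identified
#' variants against the frequency among background variants, via a
#' two-proportion chi-square test (Fisher's exact test when a margin is zero).
#'
#' @param peaks A `tf_peaks` object.
#' @param hit_variants Variant tibble of GWAS hits.
#' @param background_variants Variant tibble of background variants (may be
#'   all variants).
#' @param window Flank in bp added around each variant (default 500 kb).
#' @return One-row tibble: `freq_hits`, `freq_background`, `ratio`,
#'   `statistic`, `p_value`, `method`.
#' @export
flanking_enrichment <- function(peaks, hit_variants, background_variants,
                                window = 5e5) {
  pg <- peaks_to_granges(peaks)
  near <- function(v) {
    gr <- GenomicRanges::GRanges(
      v$chrom, IRanges::IRanges(start = pmax(1, v$pos - window), end = v$pos + window))
    IRanges::overlapsAny(gr, pg)
  }
  x_hit <- sum(near(hit_variants)); n_hit <- nrow(hit_variants)
  x_bg <- sum(near(background_variants)); n_bg <- nrow(background_variants)
  f_hit <- x_hit / n_hit
  f_bg <- x_bg / n_bg
  ratio <- if (f_bg == 0) Inf else f_hit / f_bg
  counts <- matrix(c(x_hit, n_hit - x_hit, x_bg, n_bg - x_bg), nrow = 2, byrow = TRUE)
  if (any(colSums(counts) == 0) || f_bg == 0 || f_bg == 1 || f_hit %in% c(0, 1)) {
    ft <- fisher.test(counts)
    stat <- NA_real_; p <- ft$p.value; method <- "fisher"
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value; method <- "chisq"
  }
  tibble(freq_hits = f_hit, freq_background = f_bg, ratio = ratio,
         statistic = stat, p_value = p, method = method)
}

#' Collapse multiple datasets per TF to the most significant one
#'
#' When several ChIP-seq datasets (cell lines) exist for one TF, downstream
#' analyses keep the dataset with the smallest association p-value. This is an
#' explicit post-hoc selection over a fitted results table, so it is
#' reproducible and auditable.
#'
#' @param results Tibble of per-dataset fits with at least `tf_name` and
#'   `p_value` columns (e.g. bound rows of [tidy()] outputs).
#' @return One row per `tf_name`, the smallest-p dataset (ties broken by
#'   first occurrence).
#' @export
collapse_best_dataset <- function(results) {
  results %>%
    group_by(.data$tf_name) %>%
    dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) %>%
    ungroup()
}
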