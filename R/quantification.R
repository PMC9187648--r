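QPCR_TARGETS <- c("total_archaea", "total_bacteria", "Methanobacteriales",
                  "Methanomassiliicoccales", "Methanomicrobiales",
                  "Methanimicrococcus", "Thaumarchaeota")

METHANOGEN_TARGETS <- c("Methanobacteriales", "Methanomassiliicoccales",
                        "Methanomicrobiales", "Methanimicrococcus")

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq against log10(copies/ul) over a dilution series
#' (canonically a 10-fold series from 1e9 down to 1e1 copies/ul of a plasmid
#' standard). The amplification efficiency follows from the slope as
#' E = 10^(-1/slope) - 1; a perfect doubling per cycle gives slope
#' -1/log10(2) = -3.3219 Cq per decade and E = 1.
#'
#' @param copies_per_ul known template concentrations (> 0).
#' @param cq measured quantification cycles.
#' @return `standard_curve`: list with `slope`, `intercept`, `efficiency`,
#'   `r_squared` and the points.
#' @export
fit_standard_curve <- function(copies_per_ul, cq) {
  ok <- !is.na(copies_per_ul) & !is.na(cq)
  copies_per_ul <- copies_per_ul[ok]; cq <- cq[ok]
  if (length(copies_per_ul) < 3L)
    stop("standard curve needs at least 3 points")
  if (any(copies_per_ul <= 0)) stop("standard copies must be positive")
  lx <- log10(copies_per_ul)
  if (diff(range(lx)) < 3) stop("standards must span at least 3 decades")
  if (stats::var(lx) == 0 || stats::var(cq) == 0)
    stop("zero variance in standard-curve points")
  fit <- stats::lm(cq ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("standard-curve slope must be negative")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = 1 - ss_res / ss_tot,
                 points = data.frame(copies_per_ul = copies_per_ul, cq = cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f Cq/decade, E = %.3f, R2 = %.4f\n",
              x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' A panel of qPCR measurements for one target lineage
#'
#' Holds duplicate-run Cq values per sample for one primer target, with the
#' factors needed to convert template copies/ul to 16S rRNA gene copies per
#' gram of faeces. Duplicates are stored as measured and never dropped;
#' averaging happens only at quantification time, on the copies scale.
#'
#' @param target one of the panel targets (total archaea/bacteria, the four
#'   methanogen lineages, Thaumarchaeota).
#' @param cq data.frame with columns `sample`, `run` (1/2), `cq` (`NA` = no
#'   amplification).
#' @param dilution fold dilution of the template DNA before qPCR.
#' @param per_gram_factor ul of DNA eluate per gram of sample (elution
#'   volume / extracted mass); copies/g = copies/ul x dilution x this.
#' @return `qpcr_panel` list.
#' @export
qpcr_panel <- function(target, cq, dilution = 1, per_gram_factor = 1) {
  target <- match.arg(target, QPCR_TARGETS)
  if (!all(c("sample", "run", "cq") %in% names(cq)))
    stop("cq needs columns sample, run, cq")
  if (dilution <= 0 || per_gram_factor <= 0)
    stop("dilution and per_gram_factor must be positive")
  structure(list(target = target, cq = cq, dilution = dilution,
                 per_gram_factor = per_gram_factor),
            class = "qpcr_panel")
}

#' Read qPCR run tables
#'
#' `read_qpcr_runs()` reads a CSV of per-sample Cq measurements (columns
#' `target`, `sample`, `run`, `cq`, optional `dilution`) and returns one
#' [qpcr_panel()] per target. `read_qpcr_standards()` reads a standards CSV
#' (columns `target`, `copies_per_ul`, `cq`) and fits one curve per target.
#'
#' @param path CSV path.
#' @param per_gram_factor see [qpcr_panel()].
#' @return named list of panels / of [fit_standard_curve()] objects.
#' @export
read_qpcr_runs <- function(path, per_gram_factor = 1) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "sample", "run", "cq")
  if (!all(need %in% names(raw)))
    stop("qPCR CSV needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(raw, raw$target), function(d) {
    dil <- if ("dilution" %in% names(d)) unique(d$dilution) else 1
    if (length(dil) != 1L) stop("mixed dilution factors within target")
    qpcr_panel(d$target[1L], d[c("sample", "run", "cq")], dil,
               per_gram_factor)
  })
  out
}

#' @rdname read_qpcr_runs
#' @export
read_qpcr_standards <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "copies_per_ul", "cq")
  if (!all(need %in% names(raw)))
    stop("standards CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(raw, raw$target),
         function(d) fit_standard_curve(d$copies_per_ul, d$cq))
}

#' Resolve a qPCR panel to copies per gram
#'
#' Each run's Cq is inverted through the standard curve
#' (copies/ul = 10^((Cq - intercept)/slope)), duplicate runs are averaged
#' arithmetically on the copies scale, and the result is converted to copies
#' per gram with the panel's dilution and per-gram factors. Samples with no
#' amplification in any run are reported not-detected (`NA` copies).
#'
#' @param panel a [qpcr_panel()].
#' @param curve the target's [fit_standard_curve()].
#' @return data.frame `sample`, `copies_per_g`, `n_runs`, `detected`.
#' @export
quantify <- function(panel, curve) {
  per_run <- 10^((panel$cq$cq - curve$intercept) / curve$slope)
  agg <- tapply(per_run, panel$cq$sample,
                function(v) if (all(is.na(v))) NA_real_
                            else mean(v, na.rm = TRUE))
  n_runs <- tapply(per_run, panel$cq$sample, function(v) sum(!is.na(v)))
  samples <- names(agg)
  copies_g <- as.numeric(agg) * panel$dilution * panel$per_gram_factor
  data.frame(sample = samples, copies_per_g = copies_g,
             n_runs = as.integer(n_runs), detected = !is.na(copies_g),
             row.names = NULL)
}

#' Flag samples with a low copies-to-DNA ratio
#'
#' Samples whose total bacterial 16S copy number per ng of extracted DNA is
#' anomalously low are suspect for PCR inhibition or dominance of host DNA
#' and are removed from downstream qPCR analyses. The default threshold is
#' the 2.5th percentile of the cohort's ratio distribution; an absolute
#' ratio can be supplied instead. No-amplification samples (ratio 0) with
#' measurable DNA are always removed. Samples missing a DNA concentration
#' pass through with a warning.
#'
#' @param samples character vector of sample ids.
#' @param copies total bacterial copies per gram (0 = no amplification).
#' @param dna_conc DNA concentration, ng/ul (`NA` allowed).
#' @param threshold absolute ratio threshold; `NULL` (default) uses the
#'   cohort percentile rule.
#' @param percentile cohort percentile used when `threshold` is `NULL`.
#' @return data.frame `sample`, `ratio`, `kept`.
#' @export
qc_filter_low_ratio <- function(samples, copies, dna_conc, threshold = NULL,
                                percentile = 0.025) {
  ratio <- copies / dna_conc
  if (anyNA(dna_conc))
    warning("samples without DNA concentration passed through unfiltered")
  if (is.null(threshold)) {
    threshold <- stats::quantile(ratio, percentile, na.rm = TRUE,
                                 names = FALSE)
  }
  kept <- is.na(ratio) | ratio >= threshold
  kept[!is.na(ratio) & ratio == 0 & threshold > 0] <- FALSE
  data.frame(sample = samples, ratio = ratio, kept = kept)
}

#' Total methanogen abundance per sample
#'
#' Sum of the four lineage-specific quantifications (Methanobacteriales,
#' Methanomicrobiales, Methanomassiliicoccales, Methanimicrococcus);
#' non-methanogen targets such as Thaumarchaeota are never included.
#' Not-detected lineages contribute 0 and the sample is flagged
#' `partial` when any lineage was missing.
#'
#' @param quantified named list of [quantify()] outputs, names = targets.
#' @return data.frame `sample`, `methanogen_copies_per_g`, `partial`.
#' @export
total_methanogens <- function(quantified) {
  use <- quantified[intersect(names(quantified), METHANOGEN_TARGETS)]
  if (length(use) == 0L) stop("no methanogen lineage quantifications given")
  samples <- sort(unique(unlist(lapply(use, `[[`, "sample"))))
  acc <- stats::setNames(numeric(length(samples)), samples)
  miss <- stats::setNames(logical(length(samples)), samples)
  for (q in use) {
    v <- stats::setNames(q$copies_per_g, q$sample)[samples]
    miss <- miss | is.na(v)
    acc <- acc + ifelse(is.na(v), 0, v)
  }
  data.frame(sample = samples, methanogen_copies_per_g = unname(acc),
             partial = unname(miss), row.names = NULL)
}

#' Rescale relative abundances to absolute copies per gram
#'
#' Converts an amplicon count table to absolute abundances by multiplying
#' each sample's relative composition by its qPCR-measured total archaeal
#' copies per gram. Row sums then equal the qPCR totals exactly. Samples
#' with zero reads but positive qPCR totals get an all-`NA` row and are
#' flagged.
#'
#' @param table a [feature_table()].
#' @param total_copies named numeric, copies/g per sample (names must cover
#'   the table's samples).
#' @return `absolute_abundance` matrix (samples x taxa, copies/g) with
#'   attribute `flagged` naming zero-read samples.
#' @export
scale_relative_to_absolute <- function(table, total_copies) {
  missing <- setdiff(rownames(table), names(total_copies))
  if (length(missing) > 0L)
    stop("samples without qPCR totals: ", paste(missing, collapse = ", "))
  m <- unclass(table)
  tot_reads <- rowSums(m)
  tot_copies <- total_copies[rownames(m)]
  out <- m / ifelse(tot_reads > 0, tot_reads, NA_real_) * tot_copies
  flagged <- rownames(m)[tot_reads == 0 & tot_copies > 0]
  structure(out, class = c("absolute_abundance", "matrix"), flagged = flagged)
}

# largest-remainder (Hamilton) apportionment of `total` into integer parts
# proportional to `weights`; exact total, deterministic ties by index order
#' @keywords internal
largest_remainder <- function(weights, total) {
  if (total == 0 || sum(weights) == 0) return(rep(0, length(weights)))
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Merge archaeal and bacterial tables on a common qPCR-calibrated scale
#'
#' Archaea-specific and universal-primer libraries are sequenced to very
#' different effective depths for archaea, so their counts are not directly
#' comparable. This merge rescales both blocks to a common target depth per
#' sample and then apportions reads so that the archaeal to bacterial read
#' mass equals the archaea:bacteria ratio measured by qPCR. Within-block
#' relative abundances are preserved up to integer rounding
#' (largest-remainder, so block totals are exact). Samples without a qPCR
#' ratio are dropped. Optionally a prevalence filter removes taxa present in
#' fewer than `prevalence` of the merged samples.
#'
#' @param archaeal,bacterial [feature_table()]s sharing sample ids.
#' @param ratio named numeric, archaea:bacteria copy ratio per sample (> 0).
#' @param depth target total reads per merged sample.
#' @param prevalence minimum fraction of samples a taxon must appear in
#'   (0 disables; default 0).
#' @return `feature_table` (universal primer tag) with archaeal then
#'   bacterial columns.
#' @export
merge_by_qpcr_ratio <- function(archaeal, bacterial, ratio, depth = 10000,
                                prevalence = 0) {
  shared <- intersect(rownames(archaeal), rownames(bacterial))
  shared <- shared[shared %in% names(ratio)[!is.na(ratio)]]
  if (length(shared) == 0L) stop("no samples with both tables and a ratio")
  if (any(ratio[shared] <= 0)) stop("ratios must be positive")
  both <- intersect(colnames(archaeal), colnames(bacterial))
  if (length(both) > 0L)
    stop("taxon ids shared between blocks: ", paste(both, collapse = ", "))
  a <- unclass(archaeal)[shared, , drop = FALSE]
  b <- unclass(bacterial)[shared, , drop = FALSE]
  out <- matrix(0, nrow = length(shared), ncol = ncol(a) + ncol(b),
                dimnames = list(shared, c(colnames(a), colnames(b))))
  for (s in shared) {
    r <- ratio[[s]]
    arch_total <- round(depth * r / (1 + r))
    bact_total <- depth - arch_total
    out[s, seq_len(ncol(a))] <- largest_remainder(a[s, ], arch_total)
    out[s, ncol(a) + seq_len(ncol(b))] <- largest_remainder(b[s, ], bact_total)
  }
  merged <- feature_table(out, "universal")
  if (prevalence > 0) {
    present <- colMeans(unclass(merged) > 0)
    merged <- feature_table(unclass(merged)[, present >= prevalence,
                                            drop = FALSE], "universal")
  }
  merged
}
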