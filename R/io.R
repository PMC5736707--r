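# Readers/writers for the tabular interchange formats. All tables are
# tab-separated with a header row; '.' or empty fields are missing;
# genomic coordinates are 1-based inclusive (MAF/seg convention).

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = c("NA", ".", ""), check.names = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
}

.check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop("file ", path, ": non-numeric value '", v[bad[1]],
             "' in column ", cl, " at line ", bad[1] + 1L)
      }
      df[[cl]] <- num
    }
    bad <- which(is.na(df[[cl]]))
    if (length(bad)) {
      stop("file ", path, ": missing value in column ", cl,
           " at line ", bad[1] + 1L)
    }
  }
  df
}

#' Read a force-called mutation table
#'
#' One row per (patient, sample, mutation) with alt/ref read counts; the
#' union of mutations must be force-called so every mutation has counts
#' (zero allowed) in every sample of its patient.
#'
#' @param path Path to a tab-separated file with columns `patient_id`,
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `t_alt_count`,
#'   `t_ref_count` and optional `gene`, `is_driver`.
#' @return A data.frame with one row per (patient, sample, mutation) and
#'   a `mutation_id` column (`chrom:pos:ref>alt`).
#' @export
read_mutation_table <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "sample_id", "chrom", "pos", "ref",
                      "alt", "t_alt_count", "t_ref_count"), path)
  df <- .check_numeric(df, c("pos", "t_alt_count", "t_ref_count"), path)
  if (any(df$t_alt_count < 0) || any(df$t_ref_count < 0)) {
    stop("file ", path, ": negative read counts")
  }
  df$mutation_id <- paste0(df$chrom, ":", df$pos, ":", df$ref, ">", df$alt)
  dup <- duplicated(df[c("patient_id", "sample_id", "mutation_id")])
  if (any(dup)) {
    stop("file ", path, ": duplicated mutation_id within a patient sample: ",
         df$mutation_id[which(dup)[1]])
  }
  # every mutation of a patient must have counts in every sample
  for (pid in unique(df$patient_id)) {
    sub <- df[df$patient_id == pid, ]
    tab <- table(sub$mutation_id)
    ns <- length(unique(sub$sample_id))
    if (any(tab != ns)) {
      stop("patient ", pid, ": mutation ", names(tab)[tab != ns][1],
           " lacks force-called counts in some samples")
    }
  }
  names(df)[names(df) == "t_alt_count"] <- "alt_count"
  names(df)[names(df) == "t_ref_count"] <- "ref_count"
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  if (!"is_driver" %in% names(df)) df$is_driver <- FALSE
  df$is_driver <- as.logical(df$is_driver)
  df$is_driver[is.na(df$is_driver)] <- FALSE
  df
}

#' Read an allelic copy-number segment table
#'
#' @param path Tab-separated file with columns `sample_id`, `chrom`,
#'   `start`, `end`, `total_cn`, `major_cn`, `minor_cn`; coordinates are
#'   1-based inclusive.
#' @return Validated data.frame sorted by (sample, chrom, start).
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("sample_id", "chrom", "start", "end", "total_cn",
                      "major_cn", "minor_cn"), path)
  df <- .check_numeric(df, c("start", "end", "total_cn", "major_cn",
                             "minor_cn"), path)
  if (any(df$start > df$end)) stop("file ", path, ": segment with start > end")
  if (any(df$major_cn < 1) || any(df$minor_cn < 0)) {
    stop("file ", path, ": major_cn must be >= 1 and minor_cn >= 0")
  }
  if (any(abs(df$major_cn + df$minor_cn - df$total_cn) > 0.5)) {
    stop("file ", path, ": major_cn + minor_cn inconsistent with total_cn")
  }
  df <- df[order(df$sample_id, df$chrom, df$start), ]
  # non-overlap check within (sample, chrom)
  key <- paste(df$sample_id, df$chrom)
  for (k in unique(key)) {
    sub <- df[key == k, ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      stop("file ", path, ": overlapping segments in ", k)
    }
  }
  rownames(df) <- NULL
  df
}

#' Look up the segment covering a position
#'
#' Returns the covering segment for `(sample, chrom, pos)` or a diploid
#' default (`total_cn = 2`, `major_cn = 1`, `minor_cn = 1`) with a warning
#' when no segment covers the position.
#'
#' @param segments Segment data.frame (see [read_segments()]); may be
#'   `NULL`, in which case the diploid default is returned silently.
#' @param sample_id,chrom,pos Query coordinates (1-based).
#' @return One-row data.frame with `total_cn`, `major_cn`, `minor_cn`.
#' @export
lookup_segment <- function(segments, sample_id, chrom, pos) {
  default <- data.frame(total_cn = 2, major_cn = 1L, minor_cn = 1L)
  if (is.null(segments) || !nrow(segments)) return(default)
  hit <- segments$sample_id == sample_id & segments$chrom == chrom &
    segments$start <= pos & segments$end >= pos
  if (!any(hit)) {
    warning("no segment covers ", sample_id, " ", chrom, ":", pos,
            "; assuming diploid", call. = FALSE)
    return(default)
  }
  segments[which(hit)[1], c("total_cn", "major_cn", "minor_cn")]
}

# Accept either the on-disk schema (t_alt_count/t_ref_count, no
# mutation_id) or the normalized schema produced by read_mutation_table.
normalize_mutation_table <- function(df) {
  if ("t_alt_count" %in% names(df)) names(df)[names(df) == "t_alt_count"] <- "alt_count"
  if ("t_ref_count" %in% names(df)) names(df)[names(df) == "t_ref_count"] <- "ref_count"
  if (!"mutation_id" %in% names(df)) {
    df$mutation_id <- paste0(df$chrom, ":", df$pos, ":", df$ref, ">", df$alt)
  }
  df
}

#' Read the sample timeline
#'
#' @param path Tab-separated file with columns `patient_id`, `sample_id`,
#'   `day`, `alc_per_ul`, `purity` and optional `is_relapse`.
#' @return Data.frame sorted by (patient, day); `day` is days since
#'   treatment start, `alc_per_ul` the absolute lymphocyte count per
#'   microliter, `purity` the tumor fraction in \[0, 1\].
#' @export
read_timeline <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "sample_id", "day", "alc_per_ul",
                      "purity"), path)
  df <- .check_numeric(df, c("day", "alc_per_ul", "purity"), path)
  if (any(df$purity < 0 | df$purity > 1)) {
    stop("file ", path, ": purity outside [0, 1]")
  }
  if (any(df$alc_per_ul < 0)) stop("file ", path, ": negative ALC")
  if (!"is_relapse" %in% names(df)) df$is_relapse <- FALSE
  df$is_relapse <- as.logical(df$is_relapse)
  df$is_relapse[is.na(df$is_relapse)] <- FALSE
  df <- df[order(df$patient_id, df$day), ]
  for (pid in unique(df$patient_id)) {
    d <- df$day[df$patient_id == pid]
    if (any(duplicated(d))) {
      stop("file ", path, ": patient ", pid, " has non-increasing sample days")
    }
  }
  rownames(df) <- NULL
  df
}

#' Read the clinical outcome table
#'
#' @param path Tab-separated file with columns `patient_id`,
#'   `followup_day`, `progressed` plus optional covariate flag columns.
#' @return Validated data.frame; `progressed` coerced to logical.
#' @export
read_outcomes <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("patient_id", "followup_day", "progressed"), path)
  df <- .check_numeric(df, "followup_day", path)
  if (any(df$followup_day <= 0)) stop("file ", path, ": followup_day must be > 0")
  df$progressed <- as.logical(df$progressed)
  if (anyNA(df$progressed)) stop("file ", path, ": progressed must be logical/0-1")
  df
}

#' Write the analysis report tables
#'
#' Writes per-patient cluster, shift and kinetics tables plus a
#' machine-readable JSON summary. All numeric output is written with at
#' least 6 significant digits and the RNG seed is echoed.
#'
#' @param results A `cohortfit` object from [cohort_fit()] or a list with
#'   components `clusters`, `shifts`, `kinetics` (data.frames) and `seed`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    if (is.null(df)) return(data.frame())
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 7))
    df
  }
  paths <- character(0)
  for (nm in c("clusters", "shifts", "kinetics", "survival")) {
    df <- results[[nm]]
    if (is.null(df)) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(fmt(df), p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  summ <- list(
    seed = if (is.null(results$seed)) NA else results$seed,
    n_patients = if (is.null(results$clusters)) 0L else
      length(unique(results$clusters$patient_id)),
    n_evolved = if (is.null(results$shifts)) 0L else
      length(unique(results$shifts$patient_id[results$shifts$significant]))
  )
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}
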