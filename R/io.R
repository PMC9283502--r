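# File formats and the two field experiments: FASTA in/out (IUPAC preserved),
# validated TSV count/bioassay tables, and report builders reproducing the
# survivor-vs-moribund association and the pre/post RAF-trend analyses.

#' Read a FASTA file of IUPAC nucleotide sequences
#'
#' Line-wrap and CRLF tolerant; identifiers must be unique and sequences must
#' be over the IUPAC alphabet (violations are reported with their position).
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_kdr(paste("duplicate FASTA identifier(s):", paste(unique(dup), collapse = ", ")),
             "kdr_fasta_error")
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% names(IUPAC_CODES))
    if (length(bad)) {
      stop_kdr(
        sprintf("non-IUPAC character '%s' at position %d of record '%s'",
                chars[bad[1L]], bad[1L], ids[i]),
        "kdr_fasta_error"
      )
    }
  }
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @param header optional comment line (e.g. the generating seed) written as a
#'   `;`-style comment before the records.
#' @export
write_fasta <- function(seqs, path, width = 70L, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("; ", header), con)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# internal: the 9 genotype column names used in TSV fixtures (":" and "/" are
# awkward in headers)
GENOTYPE_TSV_COLS <- c("LL_MM", "LL_MI", "LL_II", "LF_MM", "LF_MI", "LF_II",
                       "FF_MM", "FF_MI", "FF_II")

# per-locus 3-class margin columns, the shape field RAF tables are printed in
MARGIN_TSV_COLS <- c("LL", "LF", "FF", "MM", "MI", "II")

#' Read a genotype count table from TSV
#'
#' Two schemas are accepted, both with key columns `year`, `location`,
#' `group` (moribund/survivor or pre/post; `insecticide` optional) and `n`:
#' the nine-class joint columns `LL_MM ... FF_II` (glass-vial association
#' shape), or the per-locus margin columns `LL, LF, FF, MM, MI, II` (pre/post
#' field RAF shape). Row sums are validated against `n` (both margins for the
#' margin schema).
#'
#' @param path TSV file.
#' @return data.frame; attribute `"schema"` is `"joint"` or `"margins"`.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  key <- c("year", "location", "group", "n")
  miss <- setdiff(key, names(df))
  if (length(miss)) {
    stop_kdr(paste("count table missing column(s):", paste(miss, collapse = ", ")),
             "kdr_table_error")
  }
  if (all(GENOTYPE_TSV_COLS %in% names(df))) {
    schema <- "joint"
    sums <- list(rowSums(df[GENOTYPE_TSV_COLS]))
  } else if (all(MARGIN_TSV_COLS %in% names(df))) {
    schema <- "margins"
    sums <- list(rowSums(df[c("LL", "LF", "FF")]), rowSums(df[c("MM", "MI", "II")]))
  } else {
    stop_kdr("count table has neither the nine-class joint columns nor the margin columns",
             "kdr_table_error")
  }
  for (s in sums) {
    bad <- which(s != df$n)
    if (length(bad)) {
      stop_kdr(
        sprintf("genotype counts sum to %d but n = %d in row %d (%s %s %s)",
                s[bad[1L]], df$n[bad[1L]], bad[1L], df$year[bad[1L]],
                df$location[bad[1L]], df$group[bad[1L]]),
        "kdr_table_error"
      )
    }
  }
  attr(df, "schema") <- schema
  df
}

# one TSV row -> genotype_count_table
row_to_table <- function(row) {
  counts <- setNames(as.integer(unlist(row[GENOTYPE_TSV_COLS])), GENOTYPE_CLASSES_9)
  genotype_count_table(row$location, row$year, row$group, counts)
}

#' Read a bioassay dose-mortality table from TSV
#'
#' Expected columns: `population`, `treatment` (optional), `dose`, `n`,
#' `dead`; invariants validated.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_bioassay_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("population", "dose", "n", "dead")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_kdr(paste("bioassay table missing column(s):", paste(miss, collapse = ", ")),
             "kdr_table_error")
  }
  if (any(df$dead < 0 | df$dead > df$n) || any(df$dose < 0)) {
    stop_kdr("bioassay table violates 0 <= dead <= n, dose >= 0", "kdr_table_error")
  }
  df
}

#' Path to a packaged genotype-count fixture
#'
#' `"vial"` is the glass-vial survivor/moribund experiment (Table-4 shape),
#' `"field"` the pre/post field-application experiment (Table-5 shape).
#' @param which `"vial"` or `"field"`.
#' @return file path inside the installed package.
#' @export
kdr_fixture <- function(which = c("vial", "field")) {
  which <- match.arg(which)
  fn <- c(vial = "glass_vial_genotype_counts.tsv",
          field = "field_prepost_genotype_counts.tsv")[[which]]
  system.file("extdata", fn, package = "kdrmonitor", mustWork = TRUE)
}

#' Experiment 1: genotype-vs-survival association report
#'
#' For every (year, insecticide, location) stratum with both phenotype groups
#' sampled, runs the exact 2 x k test of genotype counts between moribund and
#' survivor groups and tabulates per-class percentages and percentage-point
#' shifts.
#'
#' @param counts data.frame from [read_count_table()] with `group` in
#'   moribund/survivor and an `insecticide` column.
#' @return list: `association` (one row per stratum: n per group, exact p) and
#'   `shifts` (per-class percentages and changes).
#' @export
run_association_experiment <- function(counts) {
  stopifnot(all(counts$group %in% c("moribund", "survivor")))
  key <- unique(counts[c("year", "insecticide", "location")])
  assoc <- list(); shifts <- list()
  for (i in seq_len(nrow(key))) {
    sel <- counts$year == key$year[i] & counts$insecticide == key$insecticide[i] &
      counts$location == key$location[i]
    mor <- row_to_table(counts[sel & counts$group == "moribund", ])
    sur <- row_to_table(counts[sel & counts$group == "survivor", ])
    p <- if (mor$n == 0L || sur$n == 0L) {
      NA_real_ # the paper's N/A rows: one phenotype group unobserved
    } else {
      fisher_exact(rbind(mor$counts, sur$counts))$p_value
    }
    assoc[[i]] <- data.frame(
      year = key$year[i], insecticide = key$insecticide[i],
      location = key$location[i], n_moribund = mor$n, n_survivor = sur$n,
      p_value = p, stringsAsFactors = FALSE
    )
    sh <- genotype_shift(mor, sur)
    sh <- cbind(key[i, , drop = FALSE], sh, row.names = NULL)
    shifts[[i]] <- sh
  }
  list(association = do.call(rbind, assoc), shifts = do.call(rbind, shifts))
}

#' Experiment 2: pre/post RAF and odds-ratio trend report
#'
#' Per (year, location, locus): RAF pre and post, allele-count odds ratio
#' with Wald CI and p. Per (year, locus): the interaction binomial logit GLM
#' over locations with the equal-weight pooled odds ratio, plus raw and
#' model-marginal pooled RAFs (the marginal is the inverse-logit of the
#' equal-weight mean of per-location logit RAFs).
#'
#' @param counts data.frame from [read_count_table()] with `group` in pre/post.
#' @return list: `by_location` and `pooled` data.frames.
#' @export
run_trend_experiment <- function(counts) {
  stopifnot(all(counts$group %in% c("pre", "post")))
  by_loc <- list(); pooled <- list()
  margins_of <- function(row, locus) {
    cols <- if (identical(attr(counts, "schema"), "joint")) {
      m <- marginal_counts(setNames(as.integer(unlist(row[GENOTYPE_TSV_COLS])),
                                    GENOTYPE_CLASSES_9), locus)
      return(unname(m))
    } else if (locus == "1014") c("LL", "LF", "FF") else c("MM", "MI", "II")
    as.integer(unlist(row[cols]))
  }
  for (yr in unique(counts$year)) {
    for (locus in c("1014", "918")) {
      sel <- counts[counts$year == yr, ]
      locs <- unique(sel$location)
      allele_rows <- list()
      for (l in locs) {
        pre_m <- margins_of(sel[sel$location == l & sel$group == "pre", ], locus)
        post_m <- margins_of(sel[sel$location == l & sel$group == "post", ], locus)
        pre_a <- allele_counts(pre_m, locus)
        post_a <- allele_counts(post_m, locus)
        or <- allele_or(pre_a, post_a)
        by_loc[[length(by_loc) + 1L]] <- data.frame(
          year = yr, locus = locus, location = l,
          n_pre = sum(pre_m), n_post = sum(post_m),
          raf_pre = round(raf(pre_m, locus), 1),
          raf_post = round(raf(post_m, locus), 1),
          odds_ratio = round(or$estimate, 2),
          or_lo = round(or$ci[1L], 2), or_hi = round(or$ci[2L], 2),
          p_value = or$p_value, stringsAsFactors = FALSE
        )
        allele_rows[[l]] <- rbind(
          data.frame(location = l, time = "pre", n_res = pre_a$n_res,
                     n_sus = pre_a$n_sus, stringsAsFactors = FALSE),
          data.frame(location = l, time = "post", n_res = post_a$n_res,
                     n_sus = post_a$n_sus, stringsAsFactors = FALSE)
        )
      }
      adf <- do.call(rbind, allele_rows)
      fit <- fit_allele_glm(adf)
      pool <- pooled_or(fit)
      raf_of <- function(tm) {
        sub <- adf[adf$time == tm, ]
        raw <- 100 * sum(sub$n_res) / sum(sub$n_res + sub$n_sus)
        marg <- 100 * stats::plogis(mean(stats::qlogis(
          sub$n_res / (sub$n_res + sub$n_sus))))
        c(raw = raw, marginal = marg)
      }
      pre_r <- raf_of("pre"); post_r <- raf_of("post")
      pooled[[length(pooled) + 1L]] <- data.frame(
        year = yr, locus = locus, n_locations = length(locs),
        raf_pre = round(pre_r[["raw"]], 1),
        raf_pre_model = round(pre_r[["marginal"]], 1),
        raf_post = round(post_r[["raw"]], 1),
        raf_post_model = round(post_r[["marginal"]], 1),
        odds_ratio = round(pool$estimate, 2),
        or_lo = round(pool$ci[1L], 2), or_hi = round(pool$ci[2L], 2),
        p_value = pool$p_value, stringsAsFactors = FALSE
      )
    }
  }
  list(by_location = do.call(rbind, by_loc), pooled = do.call(rbind, pooled))
}

#' Run both field experiments from packaged or user tables
#'
#' @param vial_path,field_path TSV paths (default: the packaged fixtures).
#' @param out_dir optional directory; when given, the four report tables are
#'   written as TSV and a plain-text summary as `summary.txt`.
#' @return list with `association` (experiment 1) and `trend` (experiment 2).
#' @export
run_experiment <- function(vial_path = kdr_fixture("vial"),
                           field_path = kdr_fixture("field"),
                           out_dir = NULL) {
  exp1 <- run_association_experiment(read_count_table(vial_path))
  exp2 <- run_trend_experiment(read_count_table(field_path))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, fn) {
      utils::write.table(df, file.path(out_dir, fn), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wt(exp1$association, "association_tests.tsv")
    wt(exp1$shifts, "genotype_shifts.tsv")
    wt(exp2$by_location, "raf_by_location.tsv")
    wt(exp2$pooled, "raf_pooled.tsv")
    summ <- c(
      "kdr/super-kdr resistance monitoring report",
      sprintf("experiment 1: %d strata tested (exact 2xk genotype association)",
              nrow(exp1$association)),
      sprintf("experiment 2: %d location-locus contrasts, %d pooled contrasts",
              nrow(exp2$by_location), nrow(exp2$pooled)),
      "pooled odds ratios (post vs pre, equal-weight over locations):",
      sprintf("  %s locus %s: OR %.2f (95%% CI %.2f-%.2f), p %.4g",
              exp2$pooled$year, exp2$pooled$locus, exp2$pooled$odds_ratio,
              exp2$pooled$or_lo, exp2$pooled$or_hi, exp2$pooled$p_value)
    )
    writeLines(summ, file.path(out_dir, "summary.txt"))
  }
  list(association = exp1, trend = exp2)
}
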