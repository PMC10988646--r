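# Cohort phenotype table: demographics, cognitive battery, ordinal pathology.
#
# Ordinal encodings are fixed package-wide:
#   Braak I..VI -> 1..6; CERAD No AD < Possible < Probable < Definite -> 0..3;
#   NIA-Reagan Low < Intermediate < High -> 0..2; sex male -> 0, female -> 1
#   (so a positive point-biserial R means higher expression in females).

BRAAK_LEVELS <- c("I", "II", "III", "IV", "V", "VI")
CERAD_LEVELS <- c("No AD", "Possible", "Probable", "Definite")
NIA_LEVELS   <- c("Low", "Intermediate", "High")
SEX_LEVELS   <- c("male", "female")
APOE_LEVELS  <- c("e2/e2", "e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")

#' Default cognitive domain map
#'
#' Maps the 19-test neuropsychological battery onto the five scoring
#' domains (episodic memory, semantic memory, working memory, perceptual
#' orientation, perceptual speed). Every test belongs to exactly one
#' scoring domain; tests that carry a secondary display label in figures
#' (e.g. category fluency as semantic/language) are scored once, under
#' the domain listed here. All tests are oriented higher-is-better.
#'
#' @return A named list of character vectors of test names, one element
#'   per cognitive domain; the union has 19 distinct tests.
#' @examples
#' dm <- default_domain_map()
#' length(unlist(dm))  # 19
#' @export
default_domain_map <- function() {
  list(
    epis.mem = c("word.list.recall", "word.list.recogn",
                 "east.bost.imm.recall", "east.bost.del.recall",
                 "log.mem.imm", "log.mem.del"),
    sem.mem  = c("bost.nam", "cat.fluenc", "ext.rang.voc", "read.test",
                 "compl.ideat.matr"),
    work.mem = c("dig.forw", "dig.backw", "dig.order", "alph.span"),
    perc.or  = c("progr.matr", "progr.matr.subs"),
    perc.sp  = c("numb.comp", "symb.dig.oral")
  )
}

#' All test names of the default battery
#' @return Character vector of the 19 test names.
#' @keywords internal
battery_tests <- function(dm = default_domain_map()) unname(unlist(dm))

braak_group <- function(braak_num) {
  # group is a pure function of Braak stage: I-II pooled, III, IV
  if (any(braak_num > 4L)) {
    validation_error("Braak stages V-VI fall outside the supported group scheme (I-II, III, IV)")
  }
  factor(ifelse(braak_num <= 2L, "I-II", ifelse(braak_num == 3L, "III", "IV")),
         levels = c("I-II", "III", "IV"))
}

#' Construct and validate a cohort table
#'
#' Assembles a validated per-subject phenotype table. The \code{group}
#' column (Braak I-II / III / IV) is always derived from \code{braak},
#' never taken from the input. \code{gcs} may be supplied or left NULL,
#' in which case it is computed as the mean of per-test z-scores over the
#' whole battery.
#'
#' @param df data.frame with columns \code{subject_id}, \code{age_at_death},
#'   \code{sex}, \code{education}, \code{apoe}, \code{mmse}, \code{braak},
#'   \code{cerad}, \code{nia_reagan}, \code{amyloid_6e10}, \code{tangle_at8},
#'   one numeric column per battery test, and optionally \code{gcs}.
#' @param domain_map named list mapping domains to test names
#'   (default \code{\link{default_domain_map}}).
#' @return A \code{cohort_table} (data.frame subclass) with ordinal columns
#'   as ordered factors and a derived \code{group} column.
#' @export
cohort_table <- function(df, domain_map = default_domain_map()) {
  required <- c("subject_id", "age_at_death", "sex", "education", "apoe",
                "mmse", "braak", "cerad", "nia_reagan",
                "amyloid_6e10", "tangle_at8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    schema_error(paste0("phenotype table is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  tests <- battery_tests(domain_map)
  missing_tests <- setdiff(tests, names(df))
  if (length(missing_tests)) {
    schema_error(paste0("phenotype table is missing battery test column(s): ",
                        paste(missing_tests, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    validation_error("duplicate subject_id values in phenotype table")
  }
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(as.character(x[!is.na(x)])), levels)
    if (length(bad)) {
      validation_error(sprintf("unknown %s level(s): %s (allowed: %s)",
                               what, paste(bad, collapse = ", "),
                               paste(levels, collapse = ", ")))
    }
  }
  check_levels(df$sex, SEX_LEVELS, "sex")
  check_levels(df$apoe, APOE_LEVELS, "apoe")
  check_levels(df$braak, BRAAK_LEVELS, "braak")
  check_levels(df$cerad, CERAD_LEVELS, "cerad")
  check_levels(df$nia_reagan, NIA_LEVELS, "nia_reagan")
  df$sex        <- factor(as.character(df$sex), levels = SEX_LEVELS)
  df$apoe       <- factor(as.character(df$apoe), levels = APOE_LEVELS)
  df$braak      <- factor(as.character(df$braak), levels = BRAAK_LEVELS,
                          ordered = TRUE)
  df$cerad      <- factor(as.character(df$cerad), levels = CERAD_LEVELS,
                          ordered = TRUE)
  df$nia_reagan <- factor(as.character(df$nia_reagan), levels = NIA_LEVELS,
                          ordered = TRUE)
  if (any(!is.na(df$mmse) & (df$mmse < 0 | df$mmse > 30))) {
    validation_error("mmse outside [0, 30]")
  }
  for (load in c("amyloid_6e10", "tangle_at8")) {
    if (any(!is.na(df[[load]]) & (df[[load]] < 0 | df[[load]] > 5))) {
      validation_error(sprintf("%s outside [0, 5]", load))
    }
  }
  df$group <- braak_group(as.integer(df$braak))
  if (is.null(df$gcs)) {
    zs <- vapply(tests, function(t) zscore(df[[t]]), numeric(nrow(df)))
    df$gcs <- rowMeans(zs, na.rm = TRUE)
  }
  attr(df, "domain_map") <- domain_map
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d subjects (%s)\n", nrow(x),
              paste(sprintf("%s n=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Composite cognitive-domain score
#'
#' Per-subject composite for one domain: the mean of per-test z-scores
#' (z computed across subjects within each test) over the subject's
#' non-missing mapped tests. Adding a constant to every subject's raw
#' score on a test leaves the composite unchanged.
#'
#' @param cohort a \code{\link{cohort_table}}
#' @param domain domain name present in \code{domain_map}
#' @param domain_map named list of test names per domain
#' @return Numeric vector, one value per subject.
#' @export
composite_domain_score <- function(cohort, domain,
                                   domain_map = attr(cohort, "domain_map") %||%
                                     default_domain_map()) {
  if (!domain %in% names(domain_map)) {
    usage_error(sprintf("unknown cognitive domain '%s'", domain))
  }
  tests <- domain_map[[domain]]
  zs <- vapply(tests, function(t) zscore(cohort[[t]]), numeric(nrow(cohort)))
  zs <- matrix(zs, nrow = nrow(cohort))
  score <- rowMeans(zs, na.rm = TRUE)
  all_missing <- apply(zs, 1L, function(r) all(is.na(r)))
  if (any(all_missing)) {
    validation_error(paste0("subject(s) with no non-missing test in domain '",
                            domain, "': ",
                            paste(cohort$subject_id[all_missing], collapse = ", ")))
  }
  score
}

#' Numeric phenotype encodings used by the association screen
#'
#' Expands a cohort table into the full phenotype set of the screen:
#' age, education, sex (0/1), MMSE, the global cognitive composite,
#' the five domain composites, the 19 individual tests, and the ordinal
#' pathology variables encoded numerically (Braak 1-6, CERAD 0-3,
#' NIA-Reagan 0-2, pathology loads as-is). Higher pathology and higher
#' age map to larger values, hence higher ranks.
#'
#' @param cohort a \code{\link{cohort_table}}
#' @param domain_map named list of test names per domain
#' @return Named list of numeric vectors (one per phenotype), with an
#'   attribute \code{binary} naming the phenotypes screened with the
#'   point-biserial coefficient.
#' @export
phenotype_values <- function(cohort,
                             domain_map = attr(cohort, "domain_map") %||%
                               default_domain_map()) {
  ph <- list(
    age   = cohort$age_at_death,
    educ  = cohort$education,
    sex   = as.numeric(cohort$sex) - 1,  # male 0, female 1
    mmse  = as.numeric(cohort$mmse),
    glob.cog = cohort$gcs
  )
  for (d in names(domain_map)) {
    ph[[d]] <- composite_domain_score(cohort, d, domain_map)
  }
  for (t in battery_tests(domain_map)) ph[[t]] <- as.numeric(cohort[[t]])
  ph$braak      <- as.numeric(cohort$braak)          # 1..6
  ph$cerad      <- as.numeric(cohort$cerad) - 1      # 0..3
  ph$niareagan  <- as.numeric(cohort$nia_reagan) - 1 # 0..2
  ph$amyl.6e10  <- as.numeric(cohort$amyloid_6e10)
  ph$tangle.at8 <- as.numeric(cohort$tangle_at8)
  attr(ph, "binary") <- "sex"
  ph
}
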