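#' Default recurrence-score tier thresholds
#'
#' Guideline-derived cut-offs mapping the 21-gene recurrence score (RS,
#' an integer in 0--100) to a three-tier risk label, per patient group.
#' For premenopausal node-negative (pN0) patients the guidelines print a
#' full three-way split (low RS <= 15, medium 16--25, high >= 26). For
#' postmenopausal (pN0/pN1) and premenopausal pN1 patients only the
#' chemotherapy decision boundary at RS 26 is printed, so the same
#' 15/25 interior split is used by default to guarantee a three-tier
#' label always exists; both bounds are configurable per group.
#'
#' @return A named list, one entry per patient group, each a list with
#'   `low_max` (highest RS still low risk) and `med_max` (highest RS
#'   still medium risk).
#' @export
default_tier_thresholds <- function() {
  list(
    premenopausal_pN0          = list(low_max = 15, med_max = 25),
    premenopausal_pN1          = list(low_max = 15, med_max = 25),
    postmenopausal_pN0_pN1     = list(low_max = 15, med_max = 25)
  )
}

#' Map a 21-gene recurrence score to a risk tier
#'
#' Tiers are 0 (low), 1 (medium), 2 (high): `rs <= low_max` is low,
#' `low_max < rs <= med_max` is medium, anything above is high.
#' Monotone non-decreasing in `rs` for a fixed group.
#'
#' @param rs Recurrence score(s), numeric in \[0, 100\]. Vectorised.
#' @param group Patient group, one of
#'   `"premenopausal_pN0"`, `"premenopausal_pN1"`,
#'   `"postmenopausal_pN0_pN1"`.
#' @param thresholds Threshold table as from [default_tier_thresholds()].
#' @return Integer tier(s) in `{0, 1, 2}`.
#' @examples
#' rs_to_tier(c(10, 20, 26), "premenopausal_pN0")
#' @export
rs_to_tier <- function(rs, group = "premenopausal_pN0",
                       thresholds = default_tier_thresholds()) {
  if (!group %in% names(thresholds)) {
    stop("unknown patient group: ", group, call. = FALSE)
  }
  if (any(!is.finite(rs)) || any(rs < 0 | rs > 100)) {
    stop("recurrence score must lie in [0, 100]", call. = FALSE)
  }
  th <- thresholds[[group]]
  as.integer(ifelse(rs <= th$low_max, 0L, ifelse(rs <= th$med_max, 1L, 2L)))
}

.valid_groups <- function() names(default_tier_thresholds())

#' Read and validate a case manifest
#'
#' A manifest is a CSV with header `case_id,tier[,rs,group,slide_path]`;
#' tiers are integers 0/1/2. Each row becomes one validated case record.
#' When both `rs` and `tier` are present the supplied tier wins; a
#' mismatch against [rs_to_tier()] is a warning by default and an error
#' under `strict = TRUE`.
#'
#' @param path Path to the manifest CSV.
#' @param thresholds Tier thresholds for the consistency check.
#' @param strict If `TRUE`, an rs/tier mismatch is an error.
#' @return A tibble with columns `case_id` (character), `tier` (integer),
#'   and `rs`, `group`, `slide_path` when present in the file.
#' @export
load_manifest <- function(path, thresholds = default_tier_thresholds(),
                          strict = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  required <- c("case_id", "tier")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$case_id)) {
    dup <- unique(df$case_id[duplicated(df$case_id)])
    stop("duplicate case_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tier <- suppressWarnings(as.integer(df$tier))
  if (any(is.na(tier)) || !all(tier %in% 0:2)) {
    stop("tier must be an integer in {0, 1, 2}", call. = FALSE)
  }
  df$tier <- tier
  if ("group" %in% names(df)) {
    bad <- setdiff(unique(df$group), .valid_groups())
    if (length(bad)) {
      stop("unknown patient group(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if ("rs" %in% names(df)) {
    has_rs <- !is.na(df$rs)
    if (any(has_rs)) {
      grp <- if ("group" %in% names(df)) df$group else
        rep("premenopausal_pN0", nrow(df))
      derived <- rep(NA_integer_, nrow(df))
      derived[has_rs] <- mapply(
        function(r, g) rs_to_tier(r, g, thresholds),
        df$rs[has_rs], grp[has_rs]
      )
      clash <- has_rs & derived != df$tier
      if (any(clash)) {
        msg <- paste0("tier/rs mismatch for case(s): ",
                      paste(df$case_id[clash], collapse = ", "))
        if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      }
    }
  }
  tibble::as_tibble(df)
}

#' Write a case manifest
#'
#' Inverse of [load_manifest()]; round-trips all records exactly.
#'
#' @param cohort Tibble/data frame with at least `case_id` and `tier`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tier counts of a cohort
#'
#' @param cohort Tibble with a `tier` column, or a vector of tiers.
#' @param n_classes Number of tiers (default 3); classes absent from the
#'   cohort get a zero count.
#' @return A tibble with columns `tier` and `n`; `sum(n)` equals the
#'   cohort size.
#' @export
class_distribution <- function(cohort, n_classes = 3L) {
  tiers <- if (is.data.frame(cohort)) cohort$tier else cohort
  if (length(tiers) == 0L) stop("empty cohort", call. = FALSE)
  counts <- tabulate(tiers + 1L, nbins = n_classes)
  tibble::tibble(tier = seq_len(n_classes) - 1L, n = counts)
}
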