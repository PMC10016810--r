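#' Fugl-Meyer recovery score
#'
#' Percentage of the maximal possible improvement achieved between 2 weeks
#' and 3 months post-stroke:
#' `100 * (fma_3m - fma_2w) / (66 - fma_2w)`, where 66 is the maximal
#' upper-extremity FMA score. Negative values (decline) are retained.
#'
#' @param fma_2w FMA score at 2 weeks (0..65; 66 would make the score
#'   undefined).
#' @param fma_3m FMA score at 3 months (0..66).
#' @return recovery score in percentage points (vectorized).
#' @export
fma_recovery_score <- function(fma_2w, fma_3m) {
  if (any(fma_2w < 0 | fma_2w > 66) || any(fma_3m < 0 | fma_3m > 66)) {
    stop("FMA scores must lie in [0, 66]")
  }
  if (any(fma_2w == 66)) {
    stop("recovery score undefined for fma_2w = 66 (zero denominator)")
  }
  100 * (fma_3m - fma_2w) / (66 - fma_2w)
}

#' Cortico-spinal tract FA asymmetry (Stinear's formula)
#'
#' `(fa_h - fa_l) / (fa_h + fa_l)` where `fa_h` is the mean fractional
#' anisotropy of the CST on the healthy side and `fa_l` on the lesioned side.
#' A boundary value of exactly +/-1 (one FA equal to zero) is flagged with a
#' warning as a suspicious input.
#'
#' @param fa_h mean FA of the CST contralateral to the lesion.
#' @param fa_l mean FA of the ipsilesional CST.
#' @return asymmetry index in `[-1, 1]` (vectorized).
#' @export
cst_asymmetry <- function(fa_h, fa_l) {
  if (any(fa_h + fa_l <= 0)) stop("fa_h + fa_l must be positive")
  out <- (fa_h - fa_l) / (fa_h + fa_l)
  if (any(abs(out) == 1)) {
    warning("suspicious input: asymmetry of exactly +/-1 (one FA value is zero)")
  }
  out
}

#' Lesion volume
#'
#' @param m a `lesion_mask`.
#' @param voxel_size length-3 physical voxel dimensions.
#' @return voxel count times voxel volume.
#' @export
lesion_volume <- function(m, voxel_size = c(1, 1, 1)) {
  lesion_size(m) * prod(voxel_size)
}

#' Assemble one of the five feature sets
#'
#' * Set 1: age + initial FMA.
#' * Set 2: Set 1 + lesion volume.
#' * Set 3 (benchmark): Set 2 + CST asymmetry.
#' * Set 4: Set 3 + all connectivity measures.
#' * Set 5: Set 2 + all connectivity measures (no CST asymmetry).
#'
#' Connectivity columns enter in the fixed [measure_names()] order so that
#' selection traces are reproducible. The target is the FMA recovery score,
#' or the raw 3-month FMA score when `target_kind = "outcome"`.
#'
#' @param set_id integer 1..5.
#' @param cohort a `cohort` (see [generate_cohort()]) or data.frame with
#'   columns `id, age, fma_2w, fma_3m, fa_h, fa_l, lesion_volume`.
#' @param measures patients-by-measures numeric matrix (rownames = patient
#'   ids) as produced by the pipeline; required for sets 4 and 5.
#' @param target_kind `"recovery"` (default) or `"outcome"`.
#' @return object of class `feature_table`: list with `ids`, `X` (numeric
#'   matrix), `y`, `target_kind`, `set_id`.
#' @export
assemble_feature_set <- function(set_id, cohort, measures = NULL,
                                 target_kind = c("recovery", "outcome")) {
  target_kind <- match.arg(target_kind)
  set_id <- as.integer(set_id)
  stopifnot(set_id %in% 1:5)
  df <- if (inherits(cohort, "cohort")) cohort$patients else as.data.frame(cohort)
  need <- c("id", "age", "fma_2w", "fma_3m", "fa_h", "fa_l", "lesion_volume")
  if (!all(need %in% names(df))) {
    stop("cohort table must contain columns: ", paste(need, collapse = ", "))
  }
  ids <- as.character(df$id)
  if (anyDuplicated(ids)) stop("patient ids must be unique")
  cols <- list(age = df$age, fma_2w = df$fma_2w)
  if (set_id >= 2L) cols$lesion_volume <- df$lesion_volume
  if (set_id %in% c(3L, 4L)) {
    cols$cst_asymmetry <- cst_asymmetry(df$fa_h, df$fa_l)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  if (set_id >= 4L) {
    if (is.null(measures)) stop("sets 4 and 5 require connectivity measures")
    measures <- as.matrix(measures)
    if (!all(ids %in% rownames(measures))) {
      stop("measures matrix is missing patients: ",
           paste(setdiff(ids, rownames(measures)), collapse = ", "))
    }
    keys <- intersect(measure_names(), colnames(measures))
    X <- cbind(X, measures[ids, keys, drop = FALSE])
  }
  if (anyNA(X)) stop("feature table contains missing values")
  y <- if (target_kind == "recovery") {
    fma_recovery_score(df$fma_2w, df$fma_3m)
  } else {
    as.numeric(df$fma_3m)
  }
  structure(
    list(ids = ids, X = X, y = y, target_kind = target_kind, set_id = set_id),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> set %d, %d patients x %d features, target = %s\n",
    x$set_id, nrow(x$X), ncol(x$X), x$target_kind
  ))
  invisible(x)
}
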