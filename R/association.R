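# Crossing-type association: classify lines from cross-result tables,
# build the signature-by-crossing-type 2x2, run the two-proportion test with
# Yates continuity correction, and break discordance down by signature
# category.

#' Classify a line's crossing type from its cross results
#'
#' A line is "compatible" when its males are compatible with all tested
#' females, "incompatible" when incompatible with all; mixed outcomes are
#' "undetermined" (excluded from the contingency, reported).
#'
#' @param outcomes character vector of cross outcomes for one male line,
#'   "+" (hatch) or "-" (no hatch).
#' @return one of "compatible", "incompatible", "undetermined".
#' @export
classify_crossing_type <- function(outcomes) {
  if (!length(outcomes)) abort_cid("crosses", "no cross results for line")
  bad <- setdiff(unique(outcomes), c("+", "-"))
  if (length(bad)) abort_cid("crosses", "invalid outcome(s): %s",
                             paste(bad, collapse = ", "))
  if (all(outcomes == "+")) "compatible"
  else if (all(outcomes == "-")) "incompatible"
  else "undetermined"
}

#' Build the signature-by-crossing-type contingency table
#'
#' Rows: incompatible / compatible; columns: signature-positive /
#' signature-negative. Positivity follows `positive_rule`: "any_variant"
#' (line carries the cidA delta variant or cidB a/2 — the complement of
#' "neither") or "both_variants".
#'
#' @param crossing_type character vector per line.
#' @param flags list of `cid_flags` (from [signature_flags()]) per line.
#' @param positive_rule "any_variant" (default) or "both_variants".
#' @return `cid_contingency`: 2x2 integer matrix plus undetermined count.
#' @export
build_contingency <- function(crossing_type, flags,
                              positive_rule = c("any_variant", "both_variants")) {
  positive_rule <- match.arg(positive_rule)
  if (length(crossing_type) != length(flags))
    abort_cid("contingency", "crossing_type and flags lengths differ")
  keep <- crossing_type %in% c("compatible", "incompatible")
  if (!any(keep)) abort_cid("contingency", "no classified lines")
  pos <- vapply(flags, function(f) {
    if (positive_rule == "both_variants") f$category == "both"
    else f$category != "neither"
  }, logical(1))
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("incompatible", "compatible"),
                                c("positive", "negative")))
  for (ct in rownames(tab)) {
    sel <- keep & crossing_type == ct
    tab[ct, "positive"] <- sum(sel & pos)
    tab[ct, "negative"] <- sum(sel & !pos)
  }
  structure(list(table = tab, undetermined = sum(!keep),
                 positive_rule = positive_rule),
            class = "cid_contingency")
}

#' Two-proportion test with Yates continuity correction
#'
#' For counts [[a,b],[c,d]] with N = a+b+c+d and margins r1,r2,c1,c2:
#' chi2 = N * (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2); the p-value is the
#' upper tail of the chi-square distribution with one degree of freedom.
#'
#' @param table a `cid_contingency` or a 2x2 matrix of counts.
#' @param correct apply the continuity correction (default TRUE).
#' @return `cid_assoc`: chi2, df = 1, p, corrected flag, the table.
#' @export
prop_test_yates <- function(table, correct = TRUE) {
  tab <- if (inherits(table, "cid_contingency")) table$table else table
  if (!is.matrix(tab) || any(dim(tab) != 2L) || any(tab < 0))
    abort_cid("assoc", "need a 2x2 matrix of non-negative counts")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (r1 == 0 || r2 == 0)
    abort_cid("assoc_margin", "both row totals must be positive")
  if (c1 == 0 || c2 == 0) {
    chi2 <- 0  # degenerate column: proportions equal by construction
  } else {
    num <- abs(a * d - b * c_)
    if (correct) num <- max(num - N / 2, 0)
    chi2 <- N * num^2 / (r1 * r2 * c1 * c2)
  }
  structure(list(chi2 = chi2, df = 1L,
                 p = pchisq(chi2, df = 1L, lower.tail = FALSE),
                 corrected = correct, table = tab),
            class = "cid_assoc")
}

#' @export
print.cid_assoc <- function(x, ...) {
  cat(sprintf("Two-proportion test%s: chi2 = %.4g, df = %d, p = %.3g\n",
              if (x$corrected) " (continuity-corrected)" else "",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Discordance breakdown by signature category
#'
#' @param crossing_type character vector per line.
#' @param flags list of `cid_flags` per line.
#' @return integer matrix: rows crossing types (incl. undetermined when
#'   present), columns both / cidA_only / cidB_only / neither.
#' @export
discordance_report <- function(crossing_type, flags) {
  cats <- vapply(flags, `[[`, character(1), "category")
  lv_ct <- intersect(c("incompatible", "compatible", "undetermined"),
                     unique(crossing_type))
  lv_cat <- c("both", "cidA_only", "cidB_only", "neither")
  out <- table(factor(crossing_type, levels = lv_ct),
               factor(cats, levels = lv_cat))
  m <- matrix(as.integer(out), nrow = length(lv_ct),
              dimnames = list(lv_ct, lv_cat))
  m
}
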