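# In-silico PCR-RFLP: IUPAC restriction-site scanning, double digestion,
# amplicon extraction with primer mismatch tolerance, and fragment-pattern
# variant calling. The four shipped enzymes (ApoI R^AATTY, Hpy188I TCN^GA,
# BanI G^GYRCC, TaqI T^CGA) follow standard REBASE definitions and have
# degenerate-palindromic recognitions, so forward-strand scanning suffices.

IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition string, e.g. "R AATTY" for ApoI is
#'   written "RAATTY".
#' @param cut_offset bases after the recognition start at which the enzyme
#'   cuts on the given strand (0 <= offset <= site length).
#' @return an object of class `cid_enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  bad <- setdiff(strsplit(recognition, "")[[1]], IUPAC_OK)
  if (length(bad))
    abort_cid("enzyme_iupac", "enzyme %s: invalid IUPAC code(s) %s",
              name, paste(bad, collapse = ""))
  if (!is_count(cut_offset) || cut_offset < 0 || cut_offset > nchar(recognition))
    abort_cid("enzyme", "enzyme %s: cut_offset must lie within the site", name)
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "cid_enzyme")
}

is_palindromic <- function(enz) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(enz$recognition))) == enz$recognition
}

#' Load the shipped enzyme set
#'
#' Reads `inst/extdata/enzymes.json` (editable config).
#'
#' @param path optional path to an alternative enzymes JSON.
#' @return named list of `cid_enzyme`.
#' @export
default_enzymes <- function(path = NULL) {
  cfg <- read_json(path %||% extdata_path("enzymes.json"), simplify = FALSE)
  out <- lapply(cfg, function(e) enzyme(e$name, e$recognition, e$cut_offset))
  setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Find restriction cut positions in a sequence
#'
#' Scans the forward strand for the degenerate recognition; non-palindromic
#' enzymes are additionally scanned on the reverse complement. Cut positions
#' are 0-based between-base indices (a cut at p separates bases p and p+1,
#' 1-based).
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param enz a `cid_enzyme`.
#' @return sorted integer vector of unique cut positions.
#' @export
find_sites <- function(sequence, enz) {
  stopifnot(inherits(enz, "cid_enzyme"))
  subj <- Biostrings::DNAString(toupper(sequence))
  pat <- Biostrings::DNAString(enz$recognition)
  m <- Biostrings::matchPattern(pat, subj, fixed = "subject")
  cuts <- Biostrings::start(m) - 1L + enz$cut_offset
  if (!is_palindromic(enz)) {
    mr <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                   fixed = "subject")
    # reverse-strand cut mirrored onto forward coordinates
    cuts <- c(cuts, Biostrings::end(mr) - enz$cut_offset)
  }
  cuts <- cuts[cuts >= 0 & cuts <= nchar(sequence)]
  sort(unique(as.integer(cuts)))
}

#' Digest a linear amplicon with one or more enzymes
#'
#' @param sequence the amplicon.
#' @param enzymes list of `cid_enzyme` (double digestion = two enzymes).
#' @return `cid_digest`: fragment lengths (descending), cut positions,
#'   enzyme names.
#' @export
digest <- function(sequence, enzymes) {
  if (inherits(enzymes, "cid_enzyme")) enzymes <- list(enzymes)
  if (!length(enzymes)) abort_cid("digest", "at least one enzyme required")
  n <- nchar(sequence)
  cuts <- sort(unique(unlist(lapply(enzymes, find_sites, sequence = sequence))))
  cuts <- cuts[cuts > 0 & cuts < n]
  frags <- diff(c(0L, cuts, n))
  structure(list(
    fragments = sort(as.integer(frags), decreasing = TRUE),
    cuts = as.integer(cuts),
    enzymes = vapply(enzymes, `[[`, character(1), "name"),
    length = as.integer(n)
  ), class = "cid_digest")
}

#' @export
print.cid_digest <- function(x, ...) {
  cat(sprintf("Digest (%s) of %d bp amplicon: %d fragment(s): %s\n",
              paste(x$enzymes, collapse = " + "), x$length,
              length(x$fragments), paste(x$fragments, collapse = "; ")))
  invisible(x)
}

#' In-silico PCR
#'
#' The amplicon spans from the forward primer's 5' start to the reverse
#' primer's 5' start (the reverse primer is matched as its reverse
#' complement), inclusive of both primer footprints. The leftmost valid pair
#' is chosen; several non-nested candidate amplicons raise an error.
#'
#' @param template template nucleotide string.
#' @param forward_primer,reverse_primer primer sequences, 5'->3', >= 12 nt.
#' @param max_mismatch mismatches tolerated per primer (default 0).
#' @return the amplicon sequence, with attributes `start0` and `end0`
#'   (0-based half-open span on the template).
#' @export
insilico_pcr <- function(template, forward_primer, reverse_primer,
                         max_mismatch = 0L) {
  if (nchar(forward_primer) < 12L || nchar(reverse_primer) < 12L)
    abort_cid("pcr_primer", "primers must be at least 12 nt")
  subj <- Biostrings::DNAString(toupper(template))
  fm <- Biostrings::matchPattern(Biostrings::DNAString(toupper(forward_primer)),
                                 subj, max.mismatch = max_mismatch)
  rm_ <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(toupper(reverse_primer))),
    subj, max.mismatch = max_mismatch)
  fs <- Biostrings::start(fm)
  re <- Biostrings::end(rm_)
  cand <- NULL
  for (f in sort(fs)) {
    hits <- re[re >= f + nchar(forward_primer) + nchar(reverse_primer) - 1L]
    if (length(hits)) cand <- rbind(cand, cbind(f, sort(hits)))
  }
  if (is.null(cand))
    abort_cid("pcr_no_product", "no primer pair found on template (max_mismatch=%d)",
              max_mismatch)
  # keep, per forward site, the shortest product (PCR favours short amplicons);
  # then complain if several non-nested products remain.
  per_f <- cand[!duplicated(cand[, 1]), , drop = FALSE]
  if (nrow(per_f) > 1L) {
    nested <- all(per_f[, 1] >= per_f[1, 1] & per_f[, 2] <= per_f[1, 2])
    if (!nested) {
      spans <- apply(per_f, 1L, function(r) sprintf("[%d,%d)", r[1] - 1L, r[2]))
      abort_cid("pcr_multi_product",
                "multiple non-nested candidate amplicons: %s",
                paste(spans, collapse = ", "), data = spans)
    }
  }
  f <- per_f[1, 1]; e <- per_f[1, 2]
  amp <- as.character(subj[f:e])
  attr(amp, "start0") <- f - 1L
  attr(amp, "end0") <- e
  amp
}

# ---- pattern calling --------------------------------------------------------

#' Define a reference RFLP fragment pattern
#'
#' @param name pattern name (e.g. "alpha", "beta/gamma", "delta").
#' @param fragments expected fragment lengths (bp).
#' @param discriminating logical vector, one per fragment; fragments flagged
#'   FALSE (small co-migrating bands) are ignored during matching, mirroring
#'   gel practice where only large bands discriminate variants.
#' @param tolerance match tolerance in bp (gel-resolution analogue).
#' @export
reference_pattern <- function(name, fragments, discriminating = NULL,
                              tolerance = 5L) {
  fragments <- as.integer(fragments)
  discriminating <- discriminating %||% rep(TRUE, length(fragments))
  if (length(discriminating) != length(fragments))
    abort_cid("pattern", "pattern %s: discriminating flags length mismatch", name)
  structure(list(name = name, fragments = fragments,
                 discriminating = as.logical(discriminating),
                 tolerance = as.integer(tolerance)),
            class = "cid_pattern")
}

#' Load the shipped (printed) fragment patterns for one diagnostic test
#'
#' @param test "cidA" (ApoI + Hpy188I on the 778 bp amplicon) or "cidB"
#'   (BanI + TaqI on the 1267-1276 bp amplicon).
#' @param path optional alternative patterns JSON.
#' @return list of `cid_pattern`.
#' @export
default_patterns <- function(test = c("cidA", "cidB"), path = NULL) {
  test <- match.arg(test)
  cfg <- read_json(path %||% extdata_path(sprintf("patterns_%s.json", test)),
                   simplify = FALSE)
  lapply(cfg$patterns, function(p)
    reference_pattern(p$name, unlist(p$fragments),
                      unlist(p$discriminating %||% list(NULL)),
                      p$tolerance %||% cfg$tolerance %||% 5L))
}

# one-to-one sorted matching within tolerance; valid for uniform tolerance.
frags_match <- function(observed, expected, tol) {
  if (length(observed) != length(expected)) return(FALSE)
  all(abs(sort(observed) - sort(expected)) <= tol)
}

match_one_pattern <- function(observed, pat) {
  tol <- pat$tolerance
  exp_disc <- pat$fragments[pat$discriminating]
  exp_nd <- pat$fragments[!pat$discriminating]
  obs <- sort(observed)
  # non-discriminating fragments are optional: greedily remove one observed
  # fragment within tolerance of each, if present
  for (f in exp_nd) {
    if (!length(obs)) break
    i <- which.min(abs(obs - f))
    if (abs(obs[i] - f) <= tol) obs <- obs[-i]
  }
  frags_match(obs, exp_disc, tol)
}

#' Call an RFLP pattern from digest fragments
#'
#' Returns the unique matching pattern name, `"ambiguous"` when several
#' patterns match, `"no_call"` when none does. With `mixed = TRUE` pairwise
#' pattern unions are also tried (lines carry several variants, so a digest
#' of pooled amplicons shows the union of bands); union calls are rendered
#' `"name1+name2"`.
#'
#' @param result a `cid_digest` or an integer vector of fragment lengths.
#' @param patterns list of `cid_pattern`.
#' @param mixed also consider two-pattern band unions.
#' @return character call, with attribute `matches` listing all matches.
#' @export
call_pattern <- function(result, patterns, mixed = FALSE) {
  if (!length(patterns)) abort_cid("pattern", "patterns must be non-empty")
  observed <- if (inherits(result, "cid_digest")) result$fragments else
    as.integer(result)
  hits <- character()
  for (p in patterns) if (match_one_pattern(observed, p)) hits <- c(hits, p$name)
  if (mixed && !length(hits)) {
    # band view: collapse lengths within tolerance to unique bands
    tol <- patterns[[1]]$tolerance
    bands <- function(v) {
      v <- sort(unique(v)); keep <- logical(length(v))
      last <- -Inf
      for (i in seq_along(v)) if (v[i] - last > tol) { keep[i] <- TRUE; last <- v[i] }
      v[keep]
    }
    obs_b <- bands(observed)
    nm <- vapply(patterns, `[[`, character(1), "name")
    for (i in seq_along(patterns)) for (j in seq_along(patterns)) {
      if (i >= j) next
      u <- bands(c(patterns[[i]]$fragments[patterns[[i]]$discriminating],
                   patterns[[j]]$fragments[patterns[[j]]$discriminating],
                   patterns[[i]]$fragments[!patterns[[i]]$discriminating],
                   patterns[[j]]$fragments[!patterns[[j]]$discriminating]))
      if (length(obs_b) == length(u) && all(abs(obs_b - u) <= tol))
        hits <- c(hits, paste0(nm[i], "+", nm[j]))
    }
  }
  call <- if (length(hits) == 1L) hits else if (length(hits) > 1L) "ambiguous"
          else "no_call"
  attr(call, "matches") <- hits
  call
}

# ---- constructive machinery -------------------------------------------------

# Remove every recognition site of `enzymes` from a character sequence by
# redrawing matched spans; deterministic under the caller's RNG state.
sanitize_sites <- function(seqchar, enzymes, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    dirty <- FALSE
    for (enz in enzymes) {
      subj <- Biostrings::DNAString(seqchar)
      m <- Biostrings::matchPattern(Biostrings::DNAString(enz$recognition),
                                    subj, fixed = "subject")
      if (length(m)) {
        dirty <- TRUE
        for (k in seq_along(m)) {
          s <- Biostrings::start(m)[k]; e <- Biostrings::end(m)[k]
          seqchar <- splice_chr(seqchar, s, e, random_dna(e - s + 1L))
        }
      }
    }
    if (!dirty) return(seqchar)
  }
  abort_cid("construct", "could not sanitize sequence of all enzyme sites")
}

# Concrete site sequences used when planting designed cut sites.
concrete_site <- function(enz) {
  switch(enz$name,
         ApoI = "AAATTT", Hpy188I = "TCAGA", BanI = "GGTACC", TaqI = "TCGA",
         abort_cid("construct", "no concrete site registered for enzyme %s",
                   enz$name))
}

# Plant sites so that digest(seq, enzymes) cuts exactly at `cuts` (0-based,
# named by enzyme). Backbone must already be site-free; junction-created
# spurious sites are repaired by local redraw.
plant_sites <- function(seqchar, cuts, enzymes, max_iter = 50L) {
  if (!length(cuts)) return(seqchar)
  enz_by_name <- setNames(enzymes, vapply(enzymes, `[[`, character(1), "name"))
  for (i in seq_along(cuts)) {
    enz <- enz_by_name[[names(cuts)[i]]]
    start0 <- cuts[i] - enz$cut_offset
    site <- concrete_site(enz)
    seqchar <- splice_chr(seqchar, start0 + 1L, start0 + nchar(site), site)
  }
  expected <- sort(unname(cuts))
  for (it in seq_len(max_iter)) {
    got <- sort(unique(unlist(lapply(enzymes, find_sites, sequence = seqchar))))
    got <- got[got > 0 & got < nchar(seqchar)]
    spurious <- setdiff(got, expected)
    if (!length(spurious)) {
      if (!identical(as.integer(sort(got)), as.integer(expected)))
        abort_cid("construct", "planted cut lost during repair")
      return(seqchar)
    }
    # locate and redraw one spurious site, avoiding planted footprints
    planted <- unlist(lapply(seq_along(cuts), function(i) {
      enz <- enz_by_name[[names(cuts)[i]]]
      s0 <- cuts[i] - enz$cut_offset
      seq.int(s0 + 1L, s0 + nchar(concrete_site(enz)))
    }))
    fixed_one <- FALSE
    for (enz in enzymes) {
      subj <- Biostrings::DNAString(seqchar)
      m <- Biostrings::matchPattern(Biostrings::DNAString(enz$recognition),
                                    subj, fixed = "subject")
      for (k in seq_along(m)) {
        cutpos <- Biostrings::start(m)[k] - 1L + enz$cut_offset
        if (cutpos %in% spurious) {
          span <- seq.int(Biostrings::start(m)[k], Biostrings::end(m)[k])
          free <- setdiff(span, planted)
          if (!length(free)) next
          p <- free[1]
          old <- substr(seqchar, p, p)
          seqchar <- splice_chr(seqchar, p, p, sample(setdiff(DNA_BASES, old), 1L))
          fixed_one <- TRUE
          break
        }
      }
      if (fixed_one) break
    }
    if (!fixed_one)
      abort_cid("construct", "unrepairable spurious site overlapping planted sites")
  }
  abort_cid("construct", "site planting did not converge")
}

#' Construct an amplicon realizing a fragment map
#'
#' Builds a synthetic amplicon whose digestion with the shipped enzymes cuts
#' exactly at the cumulative boundaries of `fragment_lengths` (in the given
#' order), each boundary cut by the named enzyme. Used to realize the printed
#' fragment multisets as sequences.
#'
#' @param fragment_lengths ordered fragment lengths along the amplicon.
#' @param boundary_enzymes character vector, one enzyme name per internal
#'   boundary (length = number of fragments - 1).
#' @param enzymes enzyme list (default [default_enzymes()]).
#' @param seed RNG seed for the backbone draw.
#' @return amplicon sequence string.
#' @export
amplicon_from_map <- function(fragment_lengths, boundary_enzymes,
                              enzymes = default_enzymes(), seed = 1L) {
  if (length(boundary_enzymes) != length(fragment_lengths) - 1L)
    abort_cid("construct", "need one boundary enzyme per internal boundary")
  with_seed(seed, {
    total <- sum(fragment_lengths)
    backbone <- sanitize_sites(random_dna(total), enzymes)
    cuts <- setNames(cumsum(fragment_lengths)[-length(fragment_lengths)],
                     boundary_enzymes)
    plant_sites(backbone, cuts, enzymes)
  })
}
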