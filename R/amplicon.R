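# Amplicon model for COBRA-Alu: a 117 bp amplicon interrogating two CpG
# sites whose methylation state controls TaqI digestion.

#' The four two-site methylation patterns
#'
#' A COBRA-Alu amplicon carries two interrogated CpG sites; each is either
#' methylated (`mC`) or unmethylated (`uC`), giving four molecule-level
#' patterns. `uCuC` is hypomethylated at both sites, `mCmC` hypermethylated
#' at both, and `mCuC`/`uCmC` are the two partially methylated patterns
#' (pooled as "partial" everywhere downstream, since the gel cannot tell
#' them apart once the 74/75 and 42/43 bands are pooled).
#'
#' @return Character vector of the four canonical pattern labels.
#' @examples
#' methylation_patterns()
#' @export
methylation_patterns <- function() {
  c("uCuC", "mCuC", "uCmC", "mCmC")
}

#' Methylation state of each CpG site for a pattern label
#'
#' @param pattern One of `"uCuC"`, `"mCuC"`, `"uCmC"`, `"mCmC"`.
#' @return Named logical vector `c(site1 = , site2 = )`; `TRUE` means
#'   methylated.
#' @examples
#' pattern_states("uCmC")
#' @export
pattern_states <- function(pattern) {
  pattern <- match.arg(pattern, methylation_patterns())
  c(site1 = substr(pattern, 1, 1) == "m",
    site2 = substr(pattern, 3, 3) == "m")
}

#' Pattern label from two methylation flags
#'
#' @param site1,site2 Logical; `TRUE` if the CpG at that site is methylated.
#' @return One of the four canonical labels.
#' @examples
#' pattern_label(FALSE, TRUE)  # "uCmC"
#' @export
pattern_label <- function(site1, site2) {
  stopifnot(is.logical(site1), is.logical(site2),
            length(site1) == 1L, length(site2) == 1L,
            !is.na(site1), !is.na(site2))
  paste0(if (site1) "mC" else "uC", if (site2) "mC" else "uC")
}

#' COBRA-Alu amplicon model
#'
#' Describes the PCR amplicon and its two methylation-dependent TaqI cut
#' positions. With the defaults, a cut at site 1 splits the 117 bp amplicon
#' into 43 + 74 bp, a cut at site 2 into 75 + 42 bp, and cutting at both
#' sites yields the two terminal fragments (43 and 42 bp) plus an internal
#' 32 bp fragment that falls below the gel scoring range and is never
#' measured.
#'
#' @param length Amplicon length in bp.
#' @param cut_site1,cut_site2 Cut coordinates in bp from the 5' end: a cut
#'   at coordinate `k` yields a 5' fragment of `k` bp. Must satisfy
#'   `0 < cut_site1 < cut_site2 < length`.
#' @param measurable_min Minimum fragment size (bp) scored on the gel;
#'   smaller fragments (the internal double-cut fragment with the defaults)
#'   are modeled but flagged unmeasured.
#' @return An object of class `alu_amplicon`.
#' @examples
#' alu_amplicon()
#' band_catalog(alu_amplicon())
#' @export
alu_amplicon <- function(length = 117L, cut_site1 = 43L, cut_site2 = 75L,
                         measurable_min = 40L) {
  length <- as.integer(length)
  cut_site1 <- as.integer(cut_site1)
  cut_site2 <- as.integer(cut_site2)
  measurable_min <- as.integer(measurable_min)
  if (!(0L < cut_site1 && cut_site1 < cut_site2 && cut_site2 < length)) {
    stop("invalid amplicon model: need 0 < cut_site1 < cut_site2 < length, got ",
         "cut_site1 = ", cut_site1, ", cut_site2 = ", cut_site2,
         ", length = ", length, call. = FALSE)
  }
  if (measurable_min < 0L) stop("measurable_min must be >= 0", call. = FALSE)
  structure(
    list(length = length, cut_site1 = cut_site1, cut_site2 = cut_site2,
         measurable_min = measurable_min),
    class = "alu_amplicon"
  )
}

#' @export
print.alu_amplicon <- function(x, ...) {
  cat("COBRA-Alu amplicon model\n")
  cat("  length:        ", x$length, "bp\n")
  cat("  TaqI cut sites:", x$cut_site1, "and", x$cut_site2, "bp from 5' end\n")
  cat("  gel scores fragments >=", x$measurable_min, "bp\n")
  cat("  band catalog:  ", paste(band_catalog(x), collapse = ", "), "bp\n")
  invisible(x)
}

#' In-silico bisulfite conversion
#'
#' Bisulfite treatment deaminates unmethylated cytosine to uracil, which PCR
#' reads as thymine; 5-methylcytosine is protected and remains cytosine.
#' Only the top strand is modeled.
#'
#' @param sequence A single nucleotide string over `A`, `C`, `G`, `T`.
#' @param methylated_positions Integer vector of 1-based positions of
#'   methylated cytosines; every position must index a `C`.
#' @return The converted sequence (same length).
#' @examples
#' bisulfite_convert("TCGA", 2)   # TaqI site preserved: "TCGA"
#' bisulfite_convert("TCGA")      # site destroyed: "TTGA"
#' @export
bisulfite_convert <- function(sequence, methylated_positions = integer()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(methylated_positions)) {
    methylated_positions <- as.integer(methylated_positions)
    bad <- methylated_positions[methylated_positions < 1L |
                                methylated_positions > length(chars)]
    if (length(bad)) {
      stop("methylated position out of range: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    not_c <- methylated_positions[chars[methylated_positions] != "C"]
    if (length(not_c)) {
      stop("position ", paste(not_c, collapse = ", "),
           " is not a cytosine and cannot be methylated", call. = FALSE)
    }
  }
  convert <- chars == "C"
  convert[methylated_positions] <- FALSE
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Locate TaqI recognition sites
#'
#' TaqI recognizes `TCGA`. After bisulfite conversion the site survives only
#' where the internal CpG was methylated, which is what makes the digest
#' methylation-specific.
#'
#' @param sequence A single nucleotide string.
#' @return Integer vector of 1-based motif start positions (increasing);
#'   empty if the motif is absent.
#' @examples
#' find_taqi_sites("AATCGATT")  # 3
#' @export
find_taqi_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  hits <- gregexpr("TCGA", toupper(sequence), fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

#' Digest one methylation pattern
#'
#' A TaqI cut occurs at a site if and only if that site's CpG is methylated,
#' so the number of cuts equals the number of methylated sites. Fragment
#' sizes always sum to the amplicon length; fragments below
#' `model$measurable_min` are reported as unmeasured.
#'
#' @param model An [alu_amplicon()] model.
#' @param pattern One of the four pattern labels.
#' @return A list of class `fragment_set` with elements `measured`,
#'   `unmeasured` (integer bp sizes) and `pattern`.
#' @examples
#' digest_pattern(alu_amplicon(), "uCmC")  # measured 75 and 42 bp
#' @export
digest_pattern <- function(model, pattern) {
  stopifnot(inherits(model, "alu_amplicon"))
  states <- pattern_states(pattern)
  cuts <- c(model$cut_site1, model$cut_site2)[states]
  bounds <- c(0L, cuts, model$length)
  sizes <- diff(bounds)
  measured <- sizes[sizes >= model$measurable_min]
  unmeasured <- sizes[sizes < model$measurable_min]
  structure(list(measured = as.integer(measured),
                 unmeasured = as.integer(unmeasured),
                 pattern = pattern),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("TaqI digest of pattern", x$pattern, "\n")
  cat("  measured:  ", if (length(x$measured)) paste(x$measured, collapse = ", ")
                       else "(none)", "bp\n")
  if (length(x$unmeasured))
    cat("  unmeasured:", paste(x$unmeasured, collapse = ", "), "bp\n")
  invisible(x)
}

#' Catalog of measurable band sizes
#'
#' Union of measured fragment sizes over the four patterns, deduplicated and
#' sorted descending. For the default model this is the study's five bands:
#' 117, 75, 74, 43 and 42 bp.
#'
#' @param model An [alu_amplicon()] model.
#' @return Integer vector of distinct measurable band sizes, descending.
#' @export
band_catalog <- function(model) {
  stopifnot(inherits(model, "alu_amplicon"))
  sizes <- unlist(lapply(methylation_patterns(),
                         function(p) digest_pattern(model, p)$measured))
  sort(unique(as.integer(sizes)), decreasing = TRUE)
}

#' Amplicon length from two single-cut fragment pairs
#'
#' Consistency check: each single-cut digest splits the amplicon into two
#' fragments, so both pairs must sum to the same total length.
#'
#' @param pair1,pair2 Numeric length-2 vectors of fragment sizes (bp).
#' @return The common sum (amplicon length, bp).
#' @examples
#' infer_amplicon_length(c(74, 43), c(75, 42))  # 117
#' @export
infer_amplicon_length <- function(pair1, pair2) {
  stopifnot(length(pair1) == 2L, length(pair2) == 2L,
            is.numeric(pair1), is.numeric(pair2))
  s1 <- sum(pair1); s2 <- sum(pair2)
  if (s1 != s2) {
    stop("inconsistent fragment pairs: sums ", s1, " and ", s2,
         " differ", call. = FALSE)
  }
  s1
}

#' Synthetic amplicon sequence with engineered TaqI sites
#'
#' Builds a sequence of the model's length whose only cytosines are the two
#' CpGs inside `TCGA` motifs placed so that a methylation-dependent cut at
#' each motif reproduces the model's fragment sizes (motif start = cut
#' coordinate, TaqI cutting after the leading T). Used for sequence-level
#' round-trip checks: bisulfite conversion destroys the motif exactly at
#' unmethylated sites.
#'
#' @param model An [alu_amplicon()] model.
#' @return List with `sequence` (character) and `site_starts` (1-based motif
#'   start positions, one per CpG site) and `cpg_positions` (1-based
#'   positions of the two site cytosines).
#' @export
amplicon_sequence <- function(model) {
  stopifnot(inherits(model, "alu_amplicon"))
  starts <- c(model$cut_site1, model$cut_site2)
  if (any(starts + 3L > model$length) || diff(starts) < 4L) {
    stop("cut sites too close to fit non-overlapping TCGA motifs",
         call. = FALSE)
  }
  chars <- rep(c("A", "G", "T"), length.out = model$length)
  for (s in starts) chars[s:(s + 3L)] <- c("T", "C", "G", "A")
  list(sequence = paste(chars, collapse = ""),
       site_starts = starts,
       cpg_positions = starts + 1L)
}

#' Read a single-record amplicon FASTA
#'
#' Convenience loader for a user-supplied amplicon sequence driving
#' sequence-level checks. Requires the Biostrings package.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return The sequence as an upper-case character string.
#' @export
read_amplicon_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record, found ", length(set),
         call. = FALSE)
  }
  toupper(as.character(set[[1]]))
}
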