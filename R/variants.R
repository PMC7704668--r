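#' Parse mtDNA mutation nomenclature labels
#'
#' Labels follow standard mitogenome nomenclature relative to the reference:
#' a bare position (`"16247"`) is a transition, a position with a base suffix
#' (`"9C"`) a transversion to that base, `"15+AC"` an insertion of `AC`
#' anchored after np 15, `"15d"` / `"15-17d"` a (multi-base) deletion, and
#' `"1234h"` a heteroplasmic position. `format_variant(parse_variant(x))`
#' is the identity.
#'
#' @param label character vector of variant labels.
#' @return a data frame with columns `position`, `vclass`, `derived`, `end`,
#'   `label`.
#' @export
parse_variant <- function(label) {
  label <- as.character(label)
  n <- length(label)
  out <- data.frame(position = integer(n), vclass = character(n),
                    derived = rep(NA_character_, n),
                    end = rep(NA_integer_, n),
                    label = label, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    l <- label[i]
    if (grepl("^[0-9]+$", l)) {
      out$position[i] <- as.integer(l); out$vclass[i] <- "transition"
    } else if (grepl("^[0-9]+[ACGT]$", l)) {
      out$position[i] <- as.integer(sub("[ACGT]$", "", l))
      out$vclass[i] <- "transversion"
      out$derived[i] <- substr(l, nchar(l), nchar(l))
    } else if (grepl("^[0-9]+\\+[ACGT]+$", l)) {
      p <- strsplit(l, "\\+")[[1]]
      out$position[i] <- as.integer(p[1]); out$vclass[i] <- "insertion"
      out$derived[i] <- p[2]
    } else if (grepl("^[0-9]+(-[0-9]+)?d$", l)) {
      core <- sub("d$", "", l)
      p <- as.integer(strsplit(core, "-")[[1]])
      out$position[i] <- p[1]; out$vclass[i] <- "deletion"
      out$end[i] <- if (length(p) == 2) p[2] else p[1]
    } else if (grepl("^[0-9]+h$", l)) {
      out$position[i] <- as.integer(sub("h$", "", l))
      out$vclass[i] <- "heteroplasmy"
    } else {
      stop("cannot parse variant label: ", l)
    }
  }
  out
}

#' @rdname parse_variant
#' @param variants a data frame as returned by [parse_variant()] (the
#'   `label` column is ignored and rebuilt).
#' @export
format_variant <- function(variants) {
  vapply(seq_len(nrow(variants)), function(i) {
    p <- variants$position[i]
    switch(variants$vclass[i],
      transition   = as.character(p),
      transversion = paste0(p, variants$derived[i]),
      insertion    = paste0(p, "+", variants$derived[i]),
      deletion     = {
        e <- variants$end[i]
        if (is.na(e) || e == p) paste0(p, "d") else paste0(p, "-", e, "d")
      },
      heteroplasmy = paste0(p, "h"),
      stop("unknown variant class: ", variants$vclass[i]))
  }, character(1))
}

#' Construct a variant profile
#'
#' A variant profile is a sample's set of reference-relative mutations,
#' unique by (position, class, derived state); the currency passed between
#' variant calling, haplogroup classification and tree building.
#'
#' @param sample_id sample identifier.
#' @param labels character vector of variant labels (see [parse_variant()]).
#' @return an object of class `variant_profile`.
#' @export
variant_profile <- function(sample_id, labels = character()) {
  v <- parse_variant(unique(labels))
  v <- v[order(v$position, v$vclass, v$derived, na.last = TRUE), ,
         drop = FALSE]
  rownames(v) <- NULL
  structure(list(sample_id = sample_id, variants = v),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat("variant_profile:", x$sample_id, "-", nrow(x$variants), "variants\n")
  if (nrow(x$variants))
    cat(" ", paste(x$variants$label, collapse = " "), "\n")
  invisible(x)
}

#' Globally align a mitogenome to the reference
#'
#' Banded global alignment with affine gap costs (match +1, mismatch -1, a
#' gap of length k costs 4 + k). Indels are canonicalised by 3' justification:
#' within a repeat run a gap is always placed at the highest-numbered
#' position, so variant labels are reproducible.
#'
#' @param record a single-row `mito_records` data frame, or a sequence
#'   string.
#' @param ref the reference record (or string); coordinates in the calls are
#'   1-based positions on this sequence.
#' @param band half-width of the alignment band (widened automatically when
#'   the length difference requires it).
#' @return an object of class `pairwise_alignment`: gapped `ref` and `qry`
#'   strings, the `score`, and the ids.
#' @export
align_to_reference <- function(record, ref, band = 64) {
  qid <- if (is.data.frame(record)) record$id[1] else "query"
  rid <- if (is.data.frame(ref)) ref$id[1] else "reference"
  qs <- if (is.data.frame(record)) record$sequence[1] else as.character(record)
  rs <- if (is.data.frame(ref)) ref$sequence[1] else as.character(ref)
  if (!nzchar(qs) || !nzchar(rs)) stop("empty sequence")
  if (nchar(qs) < 0.5 * nchar(rs))
    stop("sequence ", qid, " is shorter than 50% of the reference; ",
         "refusing to align a likely fragment")
  aln <- .banded_align(rs, qs, 1, -1, 4, 1, as.integer(band))
  norm <- normalize_gaps_3prime(aln$ref, aln$qry)
  structure(list(ref = norm$ref, qry = norm$qry, score = aln$score,
                 ref_id = rid, qry_id = qid),
            class = "pairwise_alignment")
}

# Shift every gap run to its 3'-most score-equivalent placement.
# Only ever exchanges a gap with an identical flanking base, so the score is
# preserved by construction. Operates on gap runs only (rare), so the cost
# is independent of alignment length once the strings are split.
normalize_gaps_3prime <- function(ref, qry) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(qry, "")[[1]]
  n <- length(r)
  shift_runs <- function(host, other) {
    # host carries the gaps being shifted; other supplies the bases
    repeat {
      moved <- FALSE
      gaps <- which(host == "-" & other != "-")
      if (!length(gaps)) break
      run_starts <- gaps[c(TRUE, diff(gaps) > 1)]
      run_ends <- gaps[c(diff(gaps) > 1, TRUE)]
      for (k in seq_along(run_starts)) {
        i <- run_starts[k]; j <- run_ends[k]
        while (j < n && host[j + 1] != "-" && other[j + 1] != "-" &&
               other[j + 1] == other[i]) {
          host[i] <- host[j + 1]; host[j + 1] <- "-"
          i <- i + 1; j <- j + 1; moved <- TRUE
        }
      }
      if (!moved) break
    }
    host
  }
  q <- shift_runs(q, r)   # deletions: gaps in the query
  r <- shift_runs(r, q)   # insertions: gaps in the reference
  list(ref = paste(r, collapse = ""), qry = paste(q, collapse = ""))
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Call variants from a pairwise alignment
#'
#' Walks the aligned columns and emits one variant per difference, in
#' reference (np) coordinates: same-class substitutions are transitions,
#' cross-class are transversions, IUPAC ambiguity codes are heteroplasmies,
#' gap runs become single insertion/deletion variants (insertions anchored
#' to the preceding np; multi-base deletions reported as a range). `N` in
#' the query is treated as missing data, not a variant.
#'
#' @param alignment a `pairwise_alignment` from [align_to_reference()].
#' @param sample_id sample id for the profile; defaults to the alignment's
#'   query id.
#' @return a [variant_profile()].
#' @export
call_variants <- function(alignment, sample_id = alignment$qry_id) {
  r <- strsplit(alignment$ref, "")[[1]]
  q <- strsplit(alignment$qry, "")[[1]]
  refpos <- cumsum(r != "-")           # np of each column's reference base
  labels <- character()

  sub_i <- which(r != "-" & q != "-" & r != q & q != "N")
  if (length(sub_i)) {
    rb <- r[sub_i]; qb <- q[sub_i]; np <- refpos[sub_i]
    het <- qb %in% AMBIG
    ts <- !het & ((rb %in% PURINES) == (qb %in% PURINES))
    labels <- c(labels,
                ifelse(het, paste0(np, "h"),
                       ifelse(ts, as.character(np), paste0(np, qb))))
  }
  runs_of <- function(idx) {
    if (!length(idx)) return(NULL)
    list(start = idx[c(TRUE, diff(idx) > 1)],
         end = idx[c(diff(idx) > 1, TRUE)])
  }
  del <- runs_of(which(q == "-"))
  if (!is.null(del)) {
    s <- refpos[del$start]; e <- refpos[del$end]
    labels <- c(labels, ifelse(s == e, paste0(s, "d"),
                               paste0(s, "-", e, "d")))
  }
  ins <- runs_of(which(r == "-"))
  if (!is.null(ins)) {
    anchor <- refpos[ins$start]        # np of the preceding reference base
    bases <- vapply(seq_along(ins$start), function(k)
      paste(q[ins$start[k]:ins$end[k]], collapse = ""), character(1))
    labels <- c(labels, paste0(anchor, "+", bases))
  }
  variant_profile(sample_id, labels)
}

#' Summarise segregating sites across profiles
#'
#' Counts the distinct variant positions segregating among a set of profiles
#' called against the same reference, and how many of those are indel sites.
#' A k-base indel counts as one site at its first affected np.
#'
#' @param profiles a list of [variant_profile()] objects.
#' @return named integer vector `c(n_variant_sites, n_indel_sites)`.
#' @export
summarize_sites <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles supplied")
  all_v <- do.call(rbind, lapply(profiles, function(p) p$variants))
  if (is.null(all_v) || nrow(all_v) == 0)
    return(c(n_variant_sites = 0L, n_indel_sites = 0L))
  key <- paste(all_v$position, all_v$vclass == "insertion")
  indel_by_site <- tapply(all_v$vclass %in% c("insertion", "deletion"),
                          key, any)
  c(n_variant_sites = length(indel_by_site),
    n_indel_sites = sum(indel_by_site))
}

#' Collapse samples into haplotypes
#'
#' Groups samples with identical variant sets; groups are ordered by size
#' (descending) and then by the lexically smallest member id, and named
#' `H1`, `H2`, ... (deterministic).
#'
#' @param profiles a list of [variant_profile()] objects.
#' @param prefix haplotype-name prefix.
#' @return a data frame with columns `haplotype`, `size`, `members`
#'   (list column of sample ids).
#' @export
collapse_haplotypes <- function(profiles, prefix = "H") {
  if (length(profiles) == 0) stop("no profiles supplied")
  keys <- vapply(profiles, function(p)
    paste(sort(p$variants$label), collapse = ";"), character(1))
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  groups <- split(ids, keys)
  members <- lapply(groups, sort)
  ord <- order(-lengths(members),
               vapply(members, `[`, character(1), 1))
  members <- members[ord]
  data.frame(haplotype = paste0(prefix, seq_along(members)),
             size = lengths(members),
             members = I(unname(members)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read variant-profile tables
#'
#' The profile table is a ragged TSV: each row is a sample id followed by
#' its tab-joined variant labels (the supplementary-figure style table).
#'
#' @param profiles list of [variant_profile()]s.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- vapply(profiles, function(p)
    paste(c(p$sample_id, p$variants$label), collapse = "\t"), character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    variant_profile(parts[1], parts[-1])
  })
}
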