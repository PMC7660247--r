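# Discontinuity (gap) analysis of identity distributions and the
# dual-threshold genus assignment rule.

#' A low-density band in an identity distribution
#'
#' Membership is strict-interior: a value v is in the band iff
#' `low < v < high`, consistent with the inclusive >= thresholds used for
#' genus assignment on either side of the band.
#'
#' @param low,high Band edges in percent (`low < high`). Defaults 74 and
#'   76, the AAI gap separating intra- from inter-genus comparisons.
#' @return A `gap_band`.
#' @export
gap_band <- function(low = 74, high = 76) {
  if (!(low < high)) stop("gap band requires low < high")
  structure(list(low = low, high = high), class = "gap_band")
}

#' Fraction of values inside a band
#'
#' @param values Numeric vector of identity values (percent), non-empty.
#' @param band A [gap_band()].
#' @return A `gap_report`: list with `band`, `n_in_band`, `n_total` and
#'   `fraction` (percent; round to one decimal at report time).
#' @export
band_fraction <- function(values, band = gap_band()) {
  if (!length(values)) stop("empty value list")
  inside <- values > band$low & values < band$high
  structure(list(band = band, n_in_band = sum(inside),
                 n_total = length(values),
                 fraction = 100 * sum(inside) / length(values)),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("Out of %d comparisons, %d (%.1f%%) were between %g and %g%%\n",
              x$n_total, x$n_in_band, x$fraction, x$band$low, x$band$high))
  invisible(x)
}

#' Detect a distribution gap between two modes
#'
#' Histograms the values at `bin_width` over `[floor(min), ceil(max)]` and
#' takes the highest-count bin as the first mode. The second mode is the
#' highest-count bin holding at least 10% of the first peak that is
#' separated from it by a low-density valley (a bin at or below 5% of the
#' smaller of the two peaks) — this keeps stray tail bins of a unimodal
#' distribution from posing as modes. The widest maximal run of
#' minimum-count bins strictly between the two modes is returned as a
#' [gap_band()]; it must be at least `min_gap_width` wide and every bin in
#' it must hold at most 5% of the smaller mode's peak count, otherwise
#' (including effectively unimodal data) `NULL` is returned.
#'
#' @param values Numeric vector (>= 10 values).
#' @param bin_width,min_gap_width Percent units.
#' @return A `gap_band` or `NULL`.
#' @export
detect_gap <- function(values, bin_width = 1, min_gap_width = 1) {
  if (length(values) < 10) stop("need at least 10 values")
  lo <- floor(min(values))
  hi <- ceiling(max(values))
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  nb <- length(counts)
  m1 <- which.max(counts)
  # second mode: the highest-count bin separated from the first by a
  # qualifying low-density valley (<= 5% of the smaller mode's peak)
  # a real second mode, not a stray tail bin: >= 10% of the first peak
  cand <- setdiff(which(counts >= 0.1 * counts[m1]), (m1 - 1):(m1 + 1))
  eligible <- Filter(function(j) {
    between <- (min(m1, j) + 1):(max(m1, j) - 1)
    min(counts[between]) <= 0.05 * min(counts[m1], counts[j])
  }, cand)
  if (!length(eligible)) return(NULL)
  m2 <- eligible[which.max(counts[eligible])]
  lo_m <- min(m1, m2); hi_m <- max(m1, m2)
  between <- (lo_m + 1):(hi_m - 1)
  cmin <- min(counts[between])
  # maximal runs of minimum-count bins between the modes
  is_min <- counts[between] == cmin
  r <- rle(is_min)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) return(NULL)
  best <- runs[which.max(r$lengths[runs])]
  run_bins <- between[starts[best]:ends[best]]
  width <- length(run_bins) * bin_width
  if (width < min_gap_width) return(NULL)
  if (any(counts[run_bins] > 0.05 * min(counts[m1], counts[m2])))
    return(NULL)
  gap_band(breaks[run_bins[1]], breaks[run_bins[length(run_bins)] + 1])
}

#' Genus membership thresholds
#'
#' `member`: minimum AAI to the type strain of the genus' type species for
#' a species to belong to that genus (>= 76% by default). `cohesion`:
#' minimum AAI that all members of one genus must share pairwise
#' (>= 74% by default). Comparisons are inclusive (>=) by default,
#' following the operative wording of the emended genus descriptions;
#' `strict_gt = TRUE` switches to strict greater-than.
#'
#' @param member,cohesion Percent thresholds, `cohesion < member`.
#' @param strict_gt Use strict `>` instead of `>=`.
#' @return A `genus_thresholds`.
#' @export
genus_thresholds <- function(member = 76, cohesion = 74, strict_gt = FALSE) {
  if (!(cohesion < member)) stop("cohesion threshold must be below member")
  structure(list(member = member, cohesion = cohesion,
                 strict_gt = strict_gt), class = "genus_thresholds")
}

.passes <- function(v, thr, strict) if (strict) v > thr else v >= thr

#' Assign strains to genera against anchor type strains
#'
#' Every anchor (the type strain of its genus' type species) defines a
#' genus. Each non-anchor strain is assigned to the anchor with which it
#' shares the highest AAI among anchors passing the `member` threshold;
#' strains passing for more than one anchor are flagged
#' `ambiguous_multi_anchor`. Strains passing for no anchor are
#' `UNASSIGNED`, with an `intermediate` flag when their best anchor AAI
#' falls strictly inside (cohesion, member) — the band where the
#' distribution gap makes membership genuinely undecidable. Finally every
#' intra-genus pair below the `cohesion` threshold raises
#' `cohesion_conflict` on both strains; conflicts are reported, never
#' silently resolved.
#'
#' @param m A `pairwise_matrix` of AAI values.
#' @param anchors Named character vector or list mapping genus name ->
#'   anchor strain id (must be in the matrix; genus names unique).
#' @param thresholds A [genus_thresholds()].
#' @return data.frame (one row per matrix strain, input order) with
#'   `strain_id, genus, anchor_aai, flags` (flags comma-separated).
#' @export
assign_genera <- function(m, anchors, thresholds = genus_thresholds()) {
  anchors <- unlist(anchors)
  if (anyDuplicated(names(anchors))) stop("duplicate genus names in anchors")
  missing <- setdiff(anchors, m$ids)
  if (length(missing)) stop("anchor strain not in matrix: ", missing[1])
  strict <- thresholds$strict_gt
  anchor_of <- stats::setNames(names(anchors), anchors)
  res <- data.frame(strain_id = m$ids, genus = NA_character_,
                    anchor_aai = NA_real_, flags = "",
                    stringsAsFactors = FALSE)
  flags <- stats::setNames(vector("list", length(m$ids)), m$ids)
  for (i in seq_along(m$ids)) {
    s <- m$ids[i]
    if (!is.na(anchor_of[s])) {
      res$genus[i] <- anchor_of[[s]]
      res$anchor_aai[i] <- 100
      next
    }
    vals <- m$values[s, anchors]
    pass <- .passes(vals, thresholds$member, strict)
    if (any(pass)) {
      best <- which(vals == max(vals[pass]) & pass)[1]
      res$genus[i] <- names(anchors)[best]
      res$anchor_aai[i] <- vals[best]
      if (sum(pass) > 1)
        flags[[s]] <- c(flags[[s]], "ambiguous_multi_anchor")
    } else {
      res$genus[i] <- "UNASSIGNED"
      best <- which.max(vals)
      res$anchor_aai[i] <- vals[best]
      if (vals[best] > thresholds$cohesion &&
          vals[best] < thresholds$member)
        flags[[s]] <- c(flags[[s]], "intermediate")
    }
  }
  # cohesion check within every assigned genus (anchors included)
  for (g in unique(res$genus[res$genus != "UNASSIGNED"])) {
    members <- res$strain_id[res$genus == g]
    if (length(members) < 2) next
    sub <- m$values[members, members, drop = FALSE]
    for (i in seq_along(members)) for (j in seq_len(i - 1)) {
      if (!.passes(sub[i, j], thresholds$cohesion, strict)) {
        flags[[members[i]]] <- c(flags[[members[i]]], "cohesion_conflict")
        flags[[members[j]]] <- c(flags[[members[j]]], "cohesion_conflict")
      }
    }
  }
  res$flags <- vapply(flags[res$strain_id], function(f)
    paste(unique(f), collapse = ","), character(1))
  res
}

#' Group unassigned strains into candidate novel genera
#'
#' Builds a graph on the unassigned strains with an edge wherever the pair
#' passes the `member` threshold; every connected component of two or more
#' strains becomes a proposed novel genus `NOVEL-k` (k in order of the
#' component's lexicographically smallest strain id). Within each
#' component the medoid — the strain with the highest mean AAI to the other
#' members — is recorded as the provisional anchor. Singletons remain
#' `UNASSIGNED`.
#'
#' @param m A `pairwise_matrix` of AAI values.
#' @param unassigned Character vector of strain ids (subset of matrix ids).
#' @param thresholds A [genus_thresholds()].
#' @return data.frame `strain_id, genus, anchor_aai, is_anchor` (empty for
#'   empty input).
#' @export
propose_novel_genera <- function(m, unassigned,
                                 thresholds = genus_thresholds()) {
  empty <- data.frame(strain_id = character(0), genus = character(0),
                      anchor_aai = numeric(0), is_anchor = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(unassigned)) return(empty)
  missing <- setdiff(unassigned, m$ids)
  if (length(missing)) stop("unassigned strain not in matrix: ", missing[1])
  strict <- thresholds$strict_gt
  sub <- m$values[unassigned, unassigned, drop = FALSE]
  adj <- .passes(sub, thresholds$member, strict)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(unassigned, comp$membership)
  multi <- groups[lengths(groups) >= 2]
  if (length(multi))
    multi <- multi[order(vapply(multi, min, character(1)))]
  out <- list()
  k <- 0
  for (grp in multi) {
    k <- k + 1
    sm <- sub[grp, grp, drop = FALSE]
    mean_aai <- (rowSums(sm) - diag(sm)) / (length(grp) - 1)
    medoid <- grp[which.max(mean_aai)]
    out[[k]] <- data.frame(strain_id = grp,
                           genus = paste0("NOVEL-", k),
                           anchor_aai = sub[grp, medoid],
                           is_anchor = grp == medoid,
                           stringsAsFactors = FALSE)
  }
  singles <- unlist(groups[lengths(groups) == 1])
  if (length(singles))
    out[[length(out) + 1]] <- data.frame(
      strain_id = singles, genus = "UNASSIGNED", anchor_aai = NA_real_,
      is_anchor = FALSE, stringsAsFactors = FALSE)
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a genus-anchor TSV (genus <TAB> strain_id)
#' @param path Two-column tab-separated file, no header.
#' @return Named character vector genus -> strain id.
#' @export
read_anchors_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("anchors TSV must have two columns")
  stats::setNames(df[[2]], df[[1]])
}
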