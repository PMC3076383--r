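#' @title Protein backbone ingestion and knot analysis
#'
#' @description
#' Proteins are modelled by their C-alpha trace: one point per residue,
#' in Angstroms.  Chains are split at structural gaps (consecutive
#' C-alpha distance above a threshold) because bridging gaps with
#' straight lines is a known source of artificial entanglement; each
#' gap-free *part* is analysed separately.  An open part is classified
#' by reducing it with MSR, closing it, re-reducing, and computing the
#' HOMFLY polynomial; the knotted core is located by trimming residues
#' from the termini until the knot vanishes.
#'
#' @name protein_io
NULL

#' Extract C-alpha backbones from PDB-format text
#'
#' Reads `ATOM` records of the first `MODEL` only; alternate location
#' indicator blank or `A`; `HETATM` excluded; one C-alpha per residue
#' (first kept).  Chains with fewer than 4 residues are skipped.
#'
#' @param pdb_text character vector of PDB lines, or a single string
#'   with embedded newlines, or a file path.
#' @param chain_filter optional chain identifiers to keep.
#' @param pdb_id identifier stored in the result (default: parsed from
#'   a `HEADER` record if present).
#' @return list of backbone chains, each a list with `pdb_id`,
#'   `chain_id` and `residues` (data.frame `resno`, `x`, `y`, `z`).
#' @export
read_backbone <- function(pdb_text, chain_filter = NULL, pdb_id = NULL) {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text))
    pdb_text <- readLines(pdb_text)
  else if (length(pdb_text) == 1L)
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  if (is.null(pdb_id)) {
    hdr <- grep("^HEADER", pdb_text, value = TRUE)
    pdb_id <- if (length(hdr)) trimws(substr(hdr[1L], 63L, 66L)) else "----"
    if (!nzchar(pdb_id)) pdb_id <- "----"
  }
  in_model <- 0L
  rows <- list()
  for (i in seq_along(pdb_text)) {
    ln <- pdb_text[i]
    rec <- substr(ln, 1L, 6L)
    if (startsWith(rec, "MODEL")) { in_model <- in_model + 1L; next }
    if (startsWith(rec, "ENDMDL")) { next }
    if (rec != "ATOM  ") next
    if (in_model > 1L) next
    atom <- trimws(substr(ln, 13L, 16L))
    if (atom != "CA") next
    alt <- substr(ln, 17L, 17L)
    if (!alt %in% c(" ", "A")) next
    ch <- substr(ln, 22L, 22L)
    if (!is.null(chain_filter) && !(ch %in% chain_filter)) next
    resno <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
    x <- suppressWarnings(as.numeric(substr(ln, 31L, 38L)))
    y <- suppressWarnings(as.numeric(substr(ln, 39L, 46L)))
    z <- suppressWarnings(as.numeric(substr(ln, 47L, 54L)))
    if (anyNA(c(resno, x, y, z)))
      stop("unparseable ATOM record at line ", i, ": ", ln)
    rows[[length(rows) + 1L]] <- data.frame(chain = ch, resno = resno,
                                            x = x, y = y, z = z)
  }
  if (length(rows) == 0L) return(list())
  df <- do.call(rbind, rows)
  out <- list()
  for (ch in unique(df$chain)) {
    sub <- df[df$chain == ch, ]
    sub <- sub[!duplicated(sub$resno), ]     # first altloc/copy kept
    if (nrow(sub) < 4L) {
      message("skipping chain ", ch, ": fewer than 4 residues")
      next
    }
    out[[length(out) + 1L]] <-
      list(pdb_id = pdb_id, chain_id = ch,
           residues = data.frame(resno = sub$resno, x = sub$x,
                                 y = sub$y, z = sub$z))
  }
  out
}

#' Split a backbone chain at structural gaps
#'
#' Gaps (consecutive C-alpha distance above `gap_threshold_A`) act as
#' chain terminators; each maximal gap-free stretch of at least 4
#' residues becomes a part, an open single-component polygonal link.
#'
#' @param chain a backbone chain from [read_backbone()].
#' @param gap_threshold_A split threshold in Angstroms.  The C-alpha
#'   virtual bond is about 3.8 A; the default 4.5 tolerates distortion
#'   while flagging true gaps.
#' @return list of parts: `chain_id`, `res_range`, `resno`, `link`.
#' @export
split_parts <- function(chain, gap_threshold_A = 4.5) {
  r <- chain$residues
  p <- as.matrix(r[, c("x", "y", "z")])
  n <- nrow(p)
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  breaks <- which(d > gap_threshold_A)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  parts <- list()
  for (i in seq_along(starts)) {
    if (ends[i] - starts[i] + 1L < 4L) next
    idx <- seq(starts[i], ends[i])
    parts[[length(parts) + 1L]] <- list(
      chain_id = chain$chain_id,
      pdb_id = chain$pdb_id,
      res_range = c(r$resno[starts[i]], r$resno[ends[i]]),
      resno = r$resno[idx],
      link = build_link(p[idx, , drop = FALSE], closed = FALSE))
  }
  parts
}

close_link_radial <- function(pts, seed) {
  ce <- colMeans(pts)
  rad <- sqrt(rowSums((pts - matrix(ce, nrow(pts), 3L, byrow = TRUE))^2))
  R <- max(rad) * 1.2 + 1
  u1 <- pts[1L, ] - ce; u1 <- u1 / max(sqrt(sum(u1^2)), 1e-12)
  u2 <- pts[nrow(pts), ] - ce; u2 <- u2 / max(sqrt(sum(u2^2)), 1e-12)
  q1 <- ce + R * u1; q2 <- ce + R * u2
  a <- ce + 2 * R * u2; b <- ce + 2 * R * u1
  mids <- rbind(q2, a)
  if (sum(u1 * u2) < 0) {           # wide angle: bisector keeps the
    w <- u1 + u2                    # outer chord outside the sphere
    if (sqrt(sum(w^2)) < 1e-6) {
      w <- c(-u1[2L], u1[1L], 0)
      if (sqrt(sum(w^2)) < 1e-6) w <- c(0, -u1[3L], u1[2L])
    }
    w <- w / sqrt(sum(w^2))
    mids <- rbind(mids, ce + 2 * R * w)
  }
  mids <- rbind(mids, b, q1)
  rbind(pts, mids)                  # closed: last point connects to first
}

#' Close an open part and classify its knot type
#'
#' The open chain is MSR-reduced, closed by the selected policy,
#' re-reduced, and its HOMFLY polynomial computed and looked up:
#'
#' * `direct`: straight segment joining the termini of the reduced
#'   chain (the reduction makes the closing segment short relative to
#'   the structure);
#' * `radial`: both termini are extended outward from the centroid to
#'   a bounding sphere and joined by a path outside it.
#'
#' If closing creates a non-simple link the termini are jittered by a
#' seeded epsilon and the closure retried (at most 10 times).
#'
#' @param part a part from [split_parts()], or any open
#'   single-component `polygonal_link`.
#' @param closure `"direct"` or `"radial"`.
#' @param seed seed for general positioning and jitter.
#' @param strategy skein crossing-selection strategy.
#' @return list `record` (from [identify_knot()]), `polynomial`
#'   (`laurent2`), `reduced_points`, `closure`.
#' @export
close_and_classify <- function(part, closure = c("direct", "radial"),
                               seed = 1L, strategy = "greedy") {
  closure <- match.arg(closure)
  link <- if (inherits(part, "polygonal_link")) part else part$link
  stopifnot(link_ncomp(link) == 1L, !link$closed[1L])
  red <- msr_reduce(link, seed = seed)$link
  pts <- red$points
  if (nrow(pts) == 2L) {     # fully straightened: trivially unknotted
    P <- l2_one()
    return(list(record = identify_knot(P), polynomial = P,
                reduced_points = 2L, closure = closure))
  }
  for (try_i in 0:10) {
    if (try_i > 0L) {
      jit <- with_seed(seed + 1000L * try_i,
                       matrix(stats::rnorm(length(pts), sd = 1e-3),
                              nrow(pts), 3L))
      pts_j <- pts + jit
    } else pts_j <- pts
    closed_pts <- if (closure == "direct") pts_j
                  else close_link_radial(pts_j, seed)
    cand <- try(build_link(closed_pts, closed = TRUE), silent = TRUE)
    if (inherits(cand, "try-error")) next
    P <- try(homfly(cand, strategy = strategy, seed = seed), silent = TRUE)
    if (inherits(P, "try-error")) next
    return(list(record = identify_knot(P), polynomial = P,
                reduced_points = nrow(red$points), closure = closure))
  }
  stop("closure failed after 10 jitter attempts")
}

part_subchain <- function(part, n_trim, c_trim) {
  pts <- part$link$points
  n <- nrow(pts)
  lo <- 1L + n_trim; hi <- n - c_trim
  if (hi - lo + 1L < 4L) return(NULL)
  build_link(pts[lo:hi, , drop = FALSE], closed = FALSE)
}

#' Knotted-core trimming
#'
#' Finds the minimal terminal trims that unknot a knotted part.
#' Residues are removed progressively from the N-terminus, with
#' re-classification after each trim, until the knot first vanishes
#' (`n_trim`); the C-terminus is then scanned with the N-side fixed
#' just short of that point (`n_trim - 1` removals, the deepest still
#' knotted prefix trim), giving `c_trim`.  Trimming `(n_trim, c_trim)`
#' jointly unknots the part.
#'
#' @param part a knotted part ([split_parts()] output entry).
#' @param closure,seed,strategy forwarded to [close_and_classify()].
#' @return list `n_trim`, `c_trim`, `knot` (the untrimmed part's knot
#'   record).
#' @export
knotted_core <- function(part, closure = "direct", seed = 1L,
                         strategy = "greedy") {
  is_knotted <- function(link) {
    if (is.null(link)) return(FALSE)
    cl <- close_and_classify(link, closure = closure, seed = seed,
                             strategy = strategy)
    cl$record$name != "U"
  }
  base <- close_and_classify(part$link, closure = closure, seed = seed,
                             strategy = strategy)
  if (base$record$name == "U") stop("nothing to core: part is not knotted")
  n <- nrow(part$link$points)
  n_trim <- NA_integer_
  for (k in seq_len(n - 4L)) {
    if (!is_knotted(part_subchain(part, k, 0L))) { n_trim <- k; break }
  }
  if (is.na(n_trim)) stop("N-terminal scan never unknotted the part")
  c_trim <- NA_integer_
  for (k in seq_len(n - n_trim + 1L - 4L)) {
    if (!is_knotted(part_subchain(part, n_trim - 1L, k))) {
      c_trim <- k; break
    }
  }
  if (is.na(c_trim)) stop("C-terminal scan never unknotted the part")
  list(n_trim = n_trim, c_trim = c_trim, knot = base$record)
}
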