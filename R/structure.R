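# Quadripartite layout detection and junction analysis.  A plastome is
# LSC + IRb + SSC + IRa on a circle; the IR pair is the longest pair of
# disjoint intervals whose sequences are exact reverse complements.  The
# canonical report frame rotates the circle so LSC starts at position 1
# and IRb precedes SSC (junction order JLB, JSB, JSA, JLA).

#' Detect the inverted-repeat pair and quadripartite layout
#'
#' Finds the longest pair of disjoint intervals on the (circular) genome
#' whose sequences are exact reverse complements of each other, with
#' nonempty gaps on both sides; the longer gap is LSC, the shorter SSC.
#' Ties are broken by maximal IR length, then by the smallest IRb start in
#' the frame where LSC starts at position 1.
#'
#' @param genome a [genome_record()] (or plain DNA string).
#' @param min_ir_len minimum IR length in bp (default 1000; plastid IRs
#'   are roughly 10--25 kb, and the floor avoids chance short palindromes).
#' @return a `quadripartite_layout`: list with `regions` (data.frame of
#'   region, start, end, length in original circular coordinates, 1-based
#'   inclusive; `end < start` denotes wrap through the origin), `junctions`
#'   (named positions JLB/JSB/JSA/JLA: the last base of LSC, IRb, SSC, IRa
#'   respectively), and `genome_length`.
#' @export
detect_inverted_repeats <- function(genome, min_ir_len = 1000) {
  s <- if (inherits(genome, "genome_record")) genome$sequence else toupper(genome)
  n <- nchar(s)
  circular <- if (inherits(genome, "genome_record")) genome$circular else TRUE
  d <- if (circular) paste0(s, s) else s
  nd <- nchar(d)
  hits <- maximal_pairs_cpp(d, revcomp(d), as.integer(min_ir_len), 0L, FALSE)
  cand <- NULL
  if (nrow(hits) > 0) {
    # map s2 (revcomp of d) starts back onto d: t(d)[j..j+L) is
    # revcomp(d[nd-j-L+2 .. nd-j+1])
    j2 <- nd - hits$j - hits$len + 2L
    a <- ((hits$i - 1L) %% n) + 1L
    b <- ((j2 - 1L) %% n) + 1L
    cand <- data.frame(a = pmin(a, b), b = pmax(a, b), len = hits$len)
    cand <- cand[cand$len * 2L < n, , drop = FALSE]
    cand <- unique(cand)
    if (nrow(cand) > 0) {
      ok <- vapply(seq_len(nrow(cand)), function(r) {
        circ_disjoint(cand$a[r], cand$len[r], cand$b[r], cand$len[r], n)
      }, TRUE)
      cand <- cand[ok, , drop = FALSE]
    }
  }
  if (is.null(cand) || nrow(cand) == 0) {
    stop(structure(class = c("no_ir_error", "error", "condition"),
                   list(message = sprintf(
                     "no inverted-repeat pair of length >= %d found: genome is not quadripartite",
                     min_ir_len), call = NULL)))
  }
  cand <- cand[cand$len == max(cand$len), , drop = FALSE]
  layouts <- lapply(seq_len(nrow(cand)), function(r)
    build_layout(cand$a[r], cand$b[r], cand$len[r], n))
  if (length(layouts) > 1) {
    # smallest IRb start in the frame where LSC starts at 1
    key <- vapply(layouts, function(L) {
      lsc_start <- L$regions$start[L$regions$region == "LSC"]
      irb_start <- L$regions$start[L$regions$region == "IRb"]
      (irb_start - lsc_start) %% n
    }, 0)
    layouts <- layouts[order(key)]
  }
  layouts[[1]]
}

# are two circular intervals (start, length) disjoint?
circ_disjoint <- function(a, la, b, lb, n) {
  pa <- ((seq(a, length.out = la) - 1L) %% n) + 1L
  # cheap check without materializing: compare on the rotated line where a -> 1
  rb <- ((b - a) %% n) + 1L      # b's start with a rotated to 1
  (rb > la) && (rb + lb - 1L <= n)
}

build_layout <- function(a, b, len, n) {
  # copies at circular starts a < b (original frame), length len.
  ea <- ((a + len - 2L) %% n) + 1L
  eb <- ((b + len - 2L) %% n) + 1L
  gap1 <- (b - (a + len)) %% n          # gap after copy A (clockwise to B)
  gap2 <- (a - (b + len)) %% n          # gap after copy B (clockwise to A)
  if (gap1 == 0L || gap2 == 0L)
    stop("IR copies are adjacent: no single-copy regions", call. = FALSE)
  if (gap1 >= gap2) {
    # LSC follows copy A: order LSC, then copy B (=IRb? no: LSC precedes IRb)
    lsc_start <- ((a + len - 1L) %% n) + 1L; lsc_len <- gap1
    irb_start <- b; ssc_start <- ((b + len - 1L) %% n) + 1L; ssc_len <- gap2
    ira_start <- a
  } else {
    lsc_start <- ((b + len - 1L) %% n) + 1L; lsc_len <- gap2
    irb_start <- a; ssc_start <- ((a + len - 1L) %% n) + 1L; ssc_len <- gap1
    ira_start <- b
  }
  ends <- function(st, l) ((st + l - 2L) %% n) + 1L
  regions <- data.frame(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(lsc_start, irb_start, ssc_start, ira_start),
    end = c(ends(lsc_start, lsc_len), ends(irb_start, len),
            ends(ssc_start, ssc_len), ends(ira_start, len)),
    length = c(lsc_len, len, ssc_len, len))
  junctions <- c(JLB = regions$end[1], JSB = regions$end[2],
                 JSA = regions$end[3], JLA = regions$end[4])
  structure(list(regions = regions, junctions = junctions, genome_length = n),
            class = "quadripartite_layout")
}

#' @export
print.quadripartite_layout <- function(x, ...) {
  cat("<quadripartite_layout>\n")
  print(x$regions, row.names = FALSE)
  cat("junctions:", paste(sprintf("%s=%d", names(x$junctions), x$junctions),
                          collapse = " "), "\n")
  invisible(x)
}

# rotate a position into the frame where LSC starts at 1
rotate_pos <- function(layout, pos) {
  lsc_start <- layout$regions$start[layout$regions$region == "LSC"]
  ((pos - lsc_start) %% layout$genome_length) + 1L
}

#' Which quadripartite region contains a position?
#' @param layout a `quadripartite_layout`.
#' @param pos 1-based position on the circle.
#' @return `"LSC"`, `"IRb"`, `"SSC"` or `"IRa"`.
#' @export
locate_region <- function(layout, pos) {
  r <- rotate_pos(layout, pos)
  lens <- layout$regions$length[match(c("LSC", "IRb", "SSC", "IRa"),
                                      layout$regions$region)]
  bounds <- cumsum(lens)
  c("LSC", "IRb", "SSC", "IRa")[which(r <= bounds)[1]]
}

#' Per-region length and GC content
#'
#' @param genome a [genome_record()].
#' @param layout the genome's `quadripartite_layout`.
#' @return data.frame of region (LSC, IRb, SSC, IRa, total), length, GC
#'   fraction, and GC percent rounded to one decimal; N bases are excluded
#'   from GC denominators.
#' @export
region_stats <- function(genome, layout) {
  s <- genome$sequence
  rows <- lapply(seq_len(nrow(layout$regions)), function(i) {
    r <- layout$regions[i, ]
    sub <- circular_substr(s, r$start, r$end)
    data.frame(region = r$region, length = r$length, gc = gc_fraction(sub))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(region = "total", length = nchar(s),
                               gc = gc_fraction(s)))
  out$gc_percent <- round(100 * out$gc, 1)
  out
}

#' Gene-to-junction distances across genomes
#'
#' For each gene of interest and each junction, reports the signed distance
#' between the gene and the junction: positive distances are the gap in bp
#' between the nearer gene end and the junction (0 when flush), negative
#' distances mean the gene crosses the junction, by that many bp into the
#' adjacent region holding the smaller part of the gene.
#'
#' @param genomes list of `list(genome =, layout =)` pairs (names used as
#'   genome labels when present).
#' @param genes_of_interest character vector of gene names.
#' @return data.frame (genome, junction, gene, region, distance, status);
#'   genes absent from a genome are recorded with status `"absent"`.
#' @export
junction_distances <- function(genomes, genes_of_interest) {
  out <- list()
  labels <- names(genomes)
  if (is.null(labels)) labels <- rep("", length(genomes))
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]$genome
    layout <- genomes[[gi]]$layout
    label <- if (nzchar(labels[gi])) labels[gi] else g$id
    n <- layout$genome_length
    # junction positions in the rotated (LSC-first) frame
    lens <- layout$regions$length[match(c("LSC", "IRb", "SSC", "IRa"),
                                        layout$regions$region)]
    jb <- cumsum(lens)
    names(jb) <- c("JLB", "JSB", "JSA", "JLA")
    ft <- g$features
    for (gene in genes_of_interest) {
      occ <- which(ft$gene == gene)
      for (jn in names(jb)) {
        if (length(occ) == 0) {
          out[[length(out) + 1L]] <- data.frame(
            genome = label, junction = jn, gene = gene, region = NA_character_,
            distance = NA_integer_, status = "absent")
          next
        }
        bx <- jb[[jn]]
        best <- NULL
        for (i in occ) {
          m <- ft$intervals[[i]]
          s0 <- rotate_pos(layout, min(m[, "start"]))
          e0 <- rotate_pos(layout, max(m[, "end"]))
          if (e0 < s0) e0 <- e0 + n   # spans the rotated origin (JLA)
          if (s0 <= bx && e0 > bx) {
            d <- -min(bx - s0 + 1L, e0 - bx)
          } else {
            # circular gap between the nearer end and the boundary
            gap_after <- min((s0 - bx - 1L) %% n, (bx - e0) %% n)
            d <- as.integer(gap_after)
          }
          if (is.null(best) || abs(d) < abs(best$d)) {
            best <- list(d = d, region = locate_region(
              layout, min(m[, "start"])))
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          genome = label, junction = jn, gene = gene, region = best$region,
          distance = as.integer(best$d), status = "present")
      }
    }
  }
  do.call(rbind, out)
}
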