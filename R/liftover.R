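# Genome-build liftover through UCSC chain files.
#
# A chain maps intervals on a source ("target" in UCSC parlance, tName)
# assembly onto a destination ("query", qName) assembly.  Header line:
#   chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd [id]
# followed by alignment data lines "size [dt dq]", coordinates 0-based
# half-open; on a '-' strand, coordinates count from the far end.

#' Parse a UCSC chain file
#'
#' @param path path to an (uncompressed or gzipped) chain file.
#' @return a `chain_map`: a tibble of ungapped alignment blocks with columns
#'   `chain_id`, `score`, `s_chrom`, `s_start`, `s_end` (0-based half-open on
#'   the source assembly), `d_chrom`, `d_size`, `d_strand`, `d_start`
#'   (block start in strand-local coordinates on the destination assembly).
#'   Blocks are ordered by descending chain score so the best-scoring chain
#'   covering a position wins.
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  blocks <- list()
  i <- 1L
  chain_no <- 0L
  while (i <= length(lines)) {
    fields <- strsplit(lines[i], "[ \t]+")[[1]]
    if (fields[1] != "chain" || length(fields) < 12) {
      abort(paste0("malformed chain header at line: ", lines[i]))
    }
    chain_no <- chain_no + 1L
    score <- as.numeric(fields[2])
    s_chrom <- normalize_chrom(fields[3])
    s_strand <- fields[5]
    if (s_strand != "+") abort("chain source strand must be '+'")
    s_pos <- as.numeric(fields[6])
    d_chrom <- normalize_chrom(fields[8])
    d_size <- as.numeric(fields[9])
    d_strand <- fields[10]
    d_pos <- as.numeric(fields[11])
    i <- i + 1L
    repeat {
      if (i > length(lines)) abort("truncated chain file: missing data lines")
      parts <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1]]))
      if (anyNA(parts)) abort(paste0("malformed chain data line: ", lines[i]))
      size <- parts[1]
      blocks[[length(blocks) + 1L]] <- tibble(
        chain_id = chain_no, score = score,
        s_chrom = s_chrom, s_start = s_pos, s_end = s_pos + size,
        d_chrom = d_chrom, d_size = d_size, d_strand = d_strand,
        d_start = d_pos)
      i <- i + 1L
      if (length(parts) == 1) break
      if (length(parts) != 3) abort("chain data lines must have 1 or 3 fields")
      s_pos <- s_pos + size + parts[2]
      d_pos <- d_pos + size + parts[3]
    }
  }
  if (length(blocks) == 0) abort("chain file contains no chains")
  out <- dplyr::bind_rows(blocks)
  out <- out[order(-out$score, out$chain_id), ]
  structure(out, class = c("chain_map", class(tibble())))
}

# map 1-based positions through the chain; returns list(chrom, pos) with NA
# where no block covers the position
map_positions <- function(chain, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  p0 <- as.numeric(pos) - 1            # 0-based
  out_chrom <- rep(NA_character_, length(pos))
  out_pos <- rep(NA_integer_, length(pos))
  for (k in seq_along(pos)) {
    hit <- which(chain$s_chrom == chrom[k] &
                 chain$s_start <= p0[k] & p0[k] < chain$s_end)
    if (length(hit) == 0) next
    b <- chain[hit[1], ]               # blocks pre-sorted by score
    q0 <- b$d_start + (p0[k] - b$s_start)
    if (b$d_strand == "-") q0 <- b$d_size - 1 - q0
    out_chrom[k] <- b$d_chrom
    out_pos[k] <- as.integer(q0 + 1)   # back to 1-based
  }
  list(chrom = out_chrom, pos = out_pos)
}

#' Lift summary-statistics coordinates between genome builds
#'
#' Maps each (chrom, pos) through the ungapped blocks of a chain file.
#' Positions falling in chain gaps or outside every chain are dropped (never
#' approximated) and counted in the report. Minus-strand destination chains
#' are reverse-coordinate mapped.
#'
#' @param ss a `sumstats` table with `chrom` and `pos`.
#' @param chain a `chain_map` from [read_chain()].
#' @return the lifted `sumstats` table; unmapped-row count recorded in
#'   [filter_log()] and attribute `"liftover_report"`.
#' @export
liftover_sumstats <- function(ss, chain) {
  if (!all(c("chrom", "pos") %in% names(ss))) {
    abort("liftover requires chrom and pos columns")
  }
  n0 <- nrow(ss)
  mapped <- map_positions(chain, ss$chrom, ss$pos)
  keep <- !is.na(mapped$pos)
  steps <- attr(ss, "steps"); cls <- class(ss)
  ss$chrom <- mapped$chrom
  ss$pos <- mapped$pos
  ss <- ss[keep, , drop = FALSE]
  attr(ss, "steps") <- steps; class(ss) <- cls
  ss <- log_step(ss, "liftover", n0, nrow(ss))
  attr(ss, "liftover_report") <- tibble(mapped = sum(keep),
                                        unmapped = n0 - sum(keep))
  ss
}
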