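#' Exact-match mappability mask
#'
#' Flags regions of a genome where short reads cannot be placed uniquely.
#' The genome is decomposed into overlapping `read_len`-bp reads (one read
#' starting every `step` bp); a read is "mappable" when its sequence occurs
#' exactly once in the genome, counting both strands. The sequence is then
#' split into consecutive `block`-bp blocks and a block is masked when the
#' fraction of reads overlapping it that are mappable falls below
#' `min_frac`. Uniqueness is decided by exact string occurrence counting of
#' canonical k-mers, so the result is deterministic and identical under
#' reverse-complementation of the whole genome. Reads containing ambiguous
#' (non-ACGT) bases are treated as never unique.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences (names become linkage-group ids).
#' @param read_len Read length in bp (default 150).
#' @param step Offset between consecutive read starts in bp (default 1).
#' @param min_frac Minimum fraction of uniquely mapping reads a block needs
#'   to stay unmasked (default 0.9).
#' @param block Block size in bp over which the fraction is evaluated
#'   (default 150).
#'
#' @return A list with `mask`, a tibble of masked intervals
#'   (`lg`, `start`, `end`; 0-based half-open, adjacent masked blocks
#'   merged), and `masked_bp`, a tibble of total masked bp per linkage group.
#' @examples
#' set.seed(1)
#' g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
#'            collapse = "")
#' exact_mappability_mask(c(lg1 = g))$masked_bp
#' @export
exact_mappability_mask <- function(fasta, read_len = 150, step = 1,
                                   min_frac = 0.9, block = 150) {
  seqs <- load_sequences(fasta)
  if (any(nchar(seqs) < read_len)) {
    abort("read_len exceeds the shortest sequence")
  }

  # enumerate reads: lg, 0-based start, sequence
  reads <- purrr::map2_dfr(names(seqs), unname(seqs), function(id, s) {
    starts <- seq(1L, nchar(s) - read_len + 1L, by = step)
    tibble(lg = id, start = starts - 1L,
           seq = substring(s, starts, starts + read_len - 1L))
  })

  ambiguous <- grepl("[^ACGT]", reads$seq)
  canon <- reads$seq
  if (any(!ambiguous)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$seq[!ambiguous])))
    canon[!ambiguous] <- pmin(reads$seq[!ambiguous], rc)
  }
  # occurrences per canonical k-mer across the genome (positions, both strands)
  counts <- table(canon[!ambiguous])
  is_unique <- !ambiguous & !is.na(match(canon, names(counts))) &
    as.vector(counts[canon]) == 1

  # distribute reads over the blocks they overlap
  b_first <- reads$start %/% block
  b_last <- (reads$start + read_len - 1L) %/% block
  n_b <- b_last - b_first + 1L
  idx <- rep(seq_len(nrow(reads)), n_b)
  per_block <- tibble(lg = reads$lg[idx],
                      blk = b_first[idx] + sequence(n_b) - 1L,
                      unique = is_unique[idx]) %>%
    group_by(.data$lg, .data$blk) %>%
    summarise(frac = mean(.data$unique), .groups = "drop")

  seq_len_bp <- setNames(nchar(seqs), names(seqs))
  masked <- per_block %>%
    filter(.data$frac < min_frac) %>%
    mutate(start = .data$blk * block,
           end = pmin((.data$blk + 1) * block,
                      unname(seq_len_bp[.data$lg]))) %>%
    select("lg", "start", "end") %>%
    arrange(.data$lg, .data$start)
  masked <- merge_adjacent(masked)

  masked_bp <- tibble(lg = names(seqs)) %>%
    left_join(masked %>% group_by(.data$lg) %>%
                summarise(masked_bp = sum(.data$end - .data$start)),
              by = "lg") %>%
    mutate(masked_bp = ifelse(is.na(.data$masked_bp), 0, .data$masked_bp))

  list(mask = masked, masked_bp = masked_bp)
}

# Internal: read FASTA via Biostrings, or pass through a named character vector
load_sequences <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && is.null(names(fasta)) &&
      file.exists(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else {
    if (is.null(names(fasta))) abort("sequences must be named")
    seqs <- setNames(toupper(as.character(fasta)), names(fasta))
  }
  seqs
}

# Internal: merge book-ended/overlapping intervals per lg
merge_adjacent <- function(x) {
  if (nrow(x) == 0) return(x)
  x <- arrange(x, .data$lg, .data$start)
  new_run <- c(TRUE, x$lg[-1] != x$lg[-nrow(x)] |
                 x$start[-1] > x$end[-nrow(x)])
  grp <- cumsum(new_run)
  x %>%
    mutate(.grp = grp) %>%
    group_by(.data$.grp) %>%
    summarise(lg = .data$lg[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop") %>%
    select("lg", "start", "end")
}
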