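AP1_CONSENSUS <- "TGASTCA" # S = C or G

#' Extract fixed-width sequence windows around probes
#'
#' Window = \[pos - width/2, pos + width/2) in 0-based coordinates, clipped
#' at chromosome ends. Sequences are uppercased; Ns are kept (they never
#' match a k-mer).
#'
#' @param mvp_set filtered MVP data.frame or probe-id character vector.
#' @param genome a [Biostrings::DNAStringSet] named by chromosome, or a
#'   FASTA file path.
#' @param manifest manifest data.frame with probe coordinates.
#' @param width window width in bp, default 100.
#' @return [Biostrings::DNAStringSet] named by probe id.
#' @export
extractWindows <- function(mvp_set, genome, manifest, width = 100L) {
  ids <- if (is.character(mvp_set)) mvp_set else mvp_set$probe_id
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  ann <- manifest[match(ids, manifest$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id))
    stop("probes absent from manifest: ",
         paste(ids[is.na(ann$probe_id)], collapse = ", "))
  miss <- setdiff(unique(ann$chrom), names(genome))
  if (length(miss))
    stop("chromosome(s) missing from FASTA: ",
         paste(miss, collapse = ", "), " (probes: ",
         paste(utils::head(ann$probe_id[ann$chrom %in% miss], 5),
               collapse = ", "), ")")
  half <- width %/% 2L
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  start0 <- pmax(ann$pos - half, 0L)               # 0-based inclusive
  end0 <- pmin(ann$pos + (width - half), chrlen[ann$chrom]) # 0-based excl.
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(ids), function(i)
    toupper(as.character(Biostrings::subseq(genome[[ann$chrom[i]]],
                                            start = start0[i] + 1L,
                                            end = end0[i]))),
    character(1)))
  names(seqs) <- ids
  seqs
}

## All k-mers of every sequence, canonicalised (k-mer collapsed with its
## reverse complement); k-mers containing N are discarded.
canonicalKmerCounts <- function(seqs, k) {
  seqs <- toupper(as.character(seqs))
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  table(canonicalKmer(kmers))
}

#' k-mer enrichment in foreground vs background windows
#'
#' A deterministic stand-in for de-novo motif discovery: every canonical
#' k-mer (collapsed with its reverse complement) is tested with a one-sided
#' binomial test of its foreground occurrence count against the rate
#' estimated from the background, and Bonferroni-corrected over the 4^k/2
#' canonical k-mers (`e_value = p * 4^k / 2`). When no background is given,
#' one is simulated per foreground window from its dinucleotide
#' (first-order Markov) composition, seeded.
#'
#' @param fg_windows foreground [Biostrings::DNAStringSet] (or character).
#' @param bg_windows background windows; NULL for the simulated background.
#' @param k k-mer size, default 8.
#' @param seed seed for the simulated background.
#' @param max_hits return at most this many top hits (default 50).
#' @return data.frame ranked by ascending `e_value` (ties: larger
#'   `fg_count`, then lexicographic k-mer): `kmer`, `fg_count`, `bg_count`,
#'   `fg_rate`, `bg_rate`, `enrichment_z`, `p`, `e_value`,
#'   `ap1_similarity`.
#' @export
kmerEnrichment <- function(fg_windows, bg_windows = NULL, k = 8L,
                           seed = 1L, max_hits = 50L) {
  fg_chr <- toupper(as.character(fg_windows))
  if (any(nchar(fg_chr) < k)) stop("k exceeds a window length")
  if (is.null(bg_windows))
    bg_windows <- markovBackground(fg_chr, seed = seed)
  bg_chr <- toupper(as.character(bg_windows))
  if (!length(bg_chr)) stop("background must be non-empty")

  fg_tab <- canonicalKmerCounts(fg_chr, k)
  bg_tab <- canonicalKmerCounts(bg_chr, k)
  fg_total <- sum(fg_tab)
  bg_total <- sum(bg_tab)

  kmers <- names(fg_tab)
  fg_count <- as.integer(fg_tab)
  bg_count <- as.integer(bg_tab[kmers])
  bg_count[is.na(bg_count)] <- 0L
  # pseudocount keeps the background rate strictly positive
  bg_rate <- (bg_count + 0.5) / (bg_total + 0.5)
  p <- stats::pbinom(fg_count - 1L, fg_total, bg_rate, lower.tail = FALSE)
  e_value <- pmin(p * 4^k / 2, Inf)
  z <- (fg_count - fg_total * bg_rate) /
    sqrt(fg_total * bg_rate * (1 - bg_rate))
  out <- data.frame(kmer = kmers, fg_count = fg_count, bg_count = bg_count,
                    fg_rate = fg_count / fg_total, bg_rate = bg_rate,
                    enrichment_z = z, p = p, e_value = e_value,
                    stringsAsFactors = FALSE)
  out <- out[order(out$e_value, -out$fg_count, out$kmer), , drop = FALSE]
  out <- utils::head(out, max_hits)
  out$ap1_similarity <- vapply(out$kmer, matchAP1, numeric(1))
  rownames(out) <- NULL
  out
}

#' Simulated dinucleotide-composition background
#'
#' For each input sequence, generates one sequence of the same length from
#' a first-order Markov chain fitted to the pooled dinucleotide
#' frequencies of the input. Deterministic given `seed`.
#'
#' @param seqs character vector of sequences.
#' @param seed integer seed.
#' @return character vector of simulated sequences.
#' @export
markovBackground <- function(seqs, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  di <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 2) return(character(0))
    substring(s, 1:(n - 1), 2:n)
  }), use.names = FALSE)
  di <- di[!grepl("N", di, fixed = TRUE)]
  trans <- matrix(1, 4, 4, dimnames = list(bases, bases)) # +1 smoothing
  tab <- table(substr(di, 1, 1), substr(di, 2, 2))
  trans[rownames(tab), colnames(tab)] <- trans[rownames(tab),
                                               colnames(tab)] + tab
  trans <- trans / rowSums(trans)
  start_p <- table(factor(substr(seqs, 1, 1), levels = bases)) + 1
  start_p <- start_p / sum(start_p)
  vapply(nchar(seqs), function(n) {
    s <- character(n)
    s[1] <- sample(bases, 1, prob = start_p)
    for (i in seq_len(n - 1))
      s[i + 1] <- sample(bases, 1, prob = trans[s[i], ])
    paste(s, collapse = "")
  }, character(1))
}

#' Similarity of a k-mer to the AP1 consensus TGA(C/G)TCA
#'
#' Best ungapped alignment of the k-mer (both strands) against the 7-base
#' consensus, scored as matching positions / 7, with S matching C or G.
#' Only full-overlap offsets are scanned, so a k-mer containing the
#' consensus scores 1.
#'
#' @param kmer character string over A/C/G/T (length >= 1).
#' @return similarity in \[0, 1\].
#' @export
matchAP1 <- function(kmer) {
  cons <- strsplit(AP1_CONSENSUS, NULL)[[1]]
  scoreOne <- function(s) {
    x <- strsplit(s, NULL)[[1]]
    L <- length(x); m <- length(cons)
    offs <- if (L >= m) 0:(L - m) else 0
    best <- 0
    for (o in offs) {
      seg <- if (L >= m) x[(o + 1):(o + m)] else c(x, rep("-", m - L))
      hits <- sum(seg == cons | (cons == "S" & seg %in% c("C", "G")))
      best <- max(best, hits / m)
    }
    best
  }
  max(scoreOne(kmer), scoreOne(revcompChar(kmer)))
}
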