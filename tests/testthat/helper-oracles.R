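# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (loops, enumeration) and independent of
# the implementation paths they check.

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all start offsets (0-based) where `pattern` occurs in `subject`,
# overlapping occurrences included, by checking every position
naive_find <- function(subject, pattern) {
  n <- nchar(subject); m <- nchar(pattern)
  if (m > n) return(integer())
  which(vapply(0:(n - m), function(off)
    substr(subject, off + 1L, off + m) == pattern, logical(1L))) - 1L
}

# complement via an explicit lookup, then reverse character by character
naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# two-sample KS statistic by scanning the pooled sorted values
naive_ks_D <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  Fa <- vapply(pool, function(t) mean(a <= t), numeric(1L))
  Fb <- vapply(pool, function(t) mean(b <= t), numeric(1L))
  max(abs(Fa - Fb))
}

# a tiny hand-laid annotation on one chromosome
tiny_annotation <- function() {
  annotation(data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(5000L, 12000L, 20000L),
    end = c(8000L, 15000L, 22000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE), c(chr1 = 30000L))
}

# uniform coverage track: value v everywhere on each chromosome
uniform_track <- function(chrom_sizes, value = 1, read_length = 50L) {
  iv <- data.frame(chrom = names(chrom_sizes), start = 0L,
                   end = unname(chrom_sizes), value = value,
                   stringsAsFactors = FALSE)
  coverage_track(iv, chrom_sizes, read_length)
}

# coverage track built from explicit per-window counts (window W),
# matching the simulator's count <-> coverage-mass convention
track_from_counts <- function(counts, chrom = "chr1", W = 200L,
                              read_length = 50L) {
  clen <- length(counts) * W
  iv <- data.frame(chrom = chrom, start = (seq_along(counts) - 1L) * W,
                   end = seq_along(counts) * W,
                   value = counts * read_length / W,
                   stringsAsFactors = FALSE)
  coverage_track(iv[iv$value > 0, ], setNames(clen, chrom), read_length)
}
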