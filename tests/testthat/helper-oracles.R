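# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# every substring of length L containing the 1-based position `pos`
oracle_windows <- function(sequence, pos, L) {
  out <- data.frame(start = integer(), peptide = character())
  for (s in seq_len(nchar(sequence))) {
    e <- s + L - 1
    if (e > nchar(sequence)) next
    if (s <= pos && pos <= e) {
      out <- rbind(out, data.frame(start = s,
                                   peptide = substr(sequence, s, e)))
    }
  }
  out
}

# positionwise product of coefficients, one lookup at a time
oracle_t_half <- function(peptide, table) {
  x <- table$constant
  for (i in seq_len(nchar(peptide))) {
    aa <- substr(peptide, i, i)
    x <- x * table$coefficients[i, aa]
  }
  unname(x)
}

# unordered pairs of k items, listed exhaustively
oracle_pair_count <- function(k) {
  n <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) n <- n + 1L
    }
  }
  n
}

random_peptide <- function(L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               L, replace = TRUE), collapse = "")
}

kit_channels <- c("PE", "APC", "Qdot605", "Qdot655", "Qdot705")
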