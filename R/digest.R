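#' In-silico protease digestion
#'
#' Canonical specificities: trypsin cleaves C-terminal to K or R except
#' when the next residue is P; AspN cleaves N-terminal to D (not E). Up
#' to \code{missed} missed cleavages are allowed.
#'
#' @param protein amino-acid string.
#' @param enzyme "trypsin" or "aspn".
#' @param missed maximum number of missed cleavages (default 1).
#' @param min_length,max_length peptide length bounds (defaults 1, Inf).
#' @return data.frame(peptide, start, end, missed) of unique peptides
#'   with their protein coordinates.
#' @export
digest_protein <- function(protein, enzyme = c("trypsin", "aspn"),
                           missed = 1L, min_length = 1L, max_length = Inf) {
  enzyme <- match.arg(enzyme)
  res <- strsplit(protein, NULL)[[1L]]
  n <- length(res)
  cut_after <- if (enzyme == "trypsin")
    which(res %in% c("K", "R") & c(res[-1L], "") != "P")
  else
    which(c(res[-1L], "") == "D")      # cut N-terminal to D
  cut_after <- cut_after[cut_after < n]
  bounds <- c(0L, cut_after, n)        # fragment i spans bounds[i]+1..bounds[i+1]
  nf <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nf)) {
    for (m in 0:missed) {
      j <- i + m
      if (j > nf) break
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < min_length || len > max_length) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(protein, s, e), start = s, end = e, missed = m)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), missed = integer(0)))
  df[!duplicated(df$peptide), , drop = FALSE]
}
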