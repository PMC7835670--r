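#' Build a junction identifier
#'
#' Junctions are keyed as `contig:donor-acceptor:strand`, where `donor` and
#' `acceptor` delimit the excised intron as a 0-based half-open interval
#' `[donor, acceptor)` on the contig, with `donor < acceptor` irrespective of
#' strand.
#'
#' @param contig Contig name.
#' @param donor 0-based first intronic base.
#' @param acceptor 0-based first exonic base after the intron (half-open end).
#' @param strand `"+"` or `"-"`.
#' @return Character junction id(s).
#' @export
junction_id <- function(contig, donor, acceptor, strand) {
  stopifnot(all(donor < acceptor))
  sprintf("%s:%d-%d:%s", contig, donor, acceptor, strand)
}

#' Parse junction identifiers
#'
#' @param jid Character vector of ids as produced by [junction_id()].
#' @return data.frame with columns `junction_id`, `contig`, `donor`,
#'   `acceptor`, `strand`.
#' @export
parse_junction_id <- function(jid) {
  m <- regmatches(jid, regexec("^(.+):([0-9]+)-([0-9]+):([+-])$", jid))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("malformed junction id: ", jid[bad][1])
  data.frame(
    junction_id = jid,
    contig = vapply(m, `[`, "", 2L),
    donor = as.integer(vapply(m, `[`, "", 3L)),
    acceptor = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

# uniform random DNA string of length n (uses current RNG state)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# all 61 non-stop codons
nonstop_codons <- function() {
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(cods, STOP_CODONS)
}

# translate a nucleotide string (character) in a given frame (0/1/2) to a
# character aa string including '*' for stops; trailing partial codon dropped
translate_frame <- function(seq, frame = 0L) {
  n <- nchar(seq)
  if (n - frame < 3L) return("")
  sub <- substr(seq, frame + 1L, frame + 3L * ((n - frame) %/% 3L))
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Write a data.frame as TSV
#'
#' Plain tab-separated output with a header row, no quoting and no row names;
#' the format used for every tabular artifact the pipeline writes.
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
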