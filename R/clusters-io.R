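# OrthoMCL-style gene-family cluster files.

#' Read an OrthoMCL-style cluster file
#'
#' One cluster per line: \code{"clusterID: species|geneID species|geneID ..."}.
#' Duplicate (species, gene) pairs within a line are collapsed with a
#' warning; a member token without the \code{|} separator is a parse error
#' reported with its line number.
#'
#' @param path cluster file.
#' @return data.frame with columns \code{cluster}, \code{species},
#'   \code{gene} (one row per member).
#' @export
readClusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(cluster = character(0), species = character(0),
                      gene = character(0), stringsAsFactors = FALSE))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(sub("\\s*:\\s*", "\x01", lines[[i]]), "\x01")[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: expected 'clusterID: members...'", i))
    cid <- trimws(parts[1L])
    toks <- strsplit(trimws(parts[2L]), "\\s+")[[1L]]
    bad <- !grepl("\\|", toks)
    if (any(bad))
      stop(sprintf("line %d: member token without species separator: %s",
                   i, toks[which(bad)[1L]]))
    sp <- sub("\\|.*$", "", toks)
    gene <- sub("^[^|]*\\|", "", toks)
    dup <- duplicated(paste(sp, gene, sep = "|"))
    if (any(dup)) {
      warning(sprintf("line %d (cluster %s): %d duplicated member(s) collapsed",
                      i, cid, sum(dup)))
      sp <- sp[!dup]; gene <- gene[!dup]
    }
    out[[i]] <- data.frame(cluster = cid, species = sp, gene = gene,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write clusters in the OrthoMCL-style text format
#' @param clusters data.frame as returned by [readClusters()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeClusters <- function(clusters, path) {
  byc <- split(clusters, factor(clusters$cluster, levels = unique(clusters$cluster)))
  lines <- vapply(byc, function(d)
    paste0(d$cluster[1L], ": ",
           paste(d$species, d$gene, sep = "|", collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
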