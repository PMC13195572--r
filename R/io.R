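## External interfaces: annotated FASTA (bases via Biostrings) with a
## chemistry sidecar, and versioned design JSON.

.DESIGN_SCHEMA_VERSION <- "1.0"

#' Write strands as annotated FASTA plus a chemistry sidecar
#'
#' Bases go to a standard FASTA file; chemistries to a sidecar with, per
#' record, a header line, a sugar line over \code{D R L M} (one character
#' per nucleotide) and a linkage line over \code{o s} (one character per
#' linkage, length = sequence length - 1). Both writers are byte-stable for
#' fixed input.
#'
#' @param strands named list of [ModifiedStrand-class] objects.
#' @param fastaFile,chemFile output paths.
#' @return invisibly, the two paths.
#' @export
writeAnnotatedFasta <- function(strands, fastaFile, chemFile) {
    seqs <- Biostrings::BStringSet(vapply(strands, function(s)
        paste(bases(s), collapse = ""), character(1)))
    names(seqs) <- vapply(strands, strandName, character(1))
    Biostrings::writeXStringSet(seqs, fastaFile)
    lines <- unlist(lapply(strands, function(s) {
        c(paste0(">", strandName(s)),
          paste(.SUGAR_CODE[sugars(s)], collapse = ""),
          paste(.LINK_CODE[linkages(s)], collapse = ""))
    }), use.names = FALSE)
    writeLines(lines, chemFile)
    invisible(c(fastaFile, chemFile))
}

#' Read annotated FASTA plus chemistry sidecar
#'
#' Rejects records whose sugar line does not match the sequence length or
#' whose linkage line is not one character shorter.
#'
#' @param fastaFile,chemFile input paths written by [writeAnnotatedFasta()].
#' @return named list of [ModifiedStrand-class] objects (loci are not part
#'   of this format).
#' @export
readAnnotatedFasta <- function(fastaFile, chemFile) {
    seqs <- Biostrings::readBStringSet(fastaFile)
    lines <- readLines(chemFile)
    hdr <- grep("^>", lines)
    if (length(hdr) != length(seqs))
        stop("sidecar record count does not match FASTA")
    sugarCode <- stats::setNames(names(.SUGAR_CODE), .SUGAR_CODE)
    linkCode <- stats::setNames(names(.LINK_CODE), .LINK_CODE)
    out <- lapply(seq_along(hdr), function(i) {
        nm <- sub("^>", "", lines[hdr[i]])
        sq <- strsplit(as.character(seqs[[match(nm, names(seqs))]]), "")[[1L]]
        sug <- strsplit(lines[hdr[i] + 1L], "")[[1L]]
        lnk <- strsplit(lines[hdr[i] + 2L], "")[[1L]]
        if (length(sug) != length(sq))
            stop(sprintf("record '%s': sugar line length %d != sequence length %d",
                nm, length(sug), length(sq)))
        if (length(lnk) != length(sq) - 1L)
            stop(sprintf("record '%s': linkage line must have length %d",
                nm, length(sq) - 1L))
        modifiedStrand(nm, sq, unname(sugarCode[sug]), unname(linkCode[lnk]))
    })
    names(out) <- vapply(out, strandName, character(1))
    out
}

.strandToList <- function(s) {
    list(name = strandName(s),
         bases = paste(bases(s), collapse = ""),
         sugars = paste(.SUGAR_CODE[sugars(s)], collapse = ""),
         linkages = paste(.LINK_CODE[linkages(s)], collapse = ""),
         loci = lapply(loci(s), as.integer))
}

.strandFromList <- function(x) {
    sugarCode <- stats::setNames(names(.SUGAR_CODE), .SUGAR_CODE)
    linkCode <- stats::setNames(names(.LINK_CODE), .LINK_CODE)
    modifiedStrand(x$name, x$bases,
        unname(sugarCode[strsplit(x$sugars, "")[[1L]]]),
        unname(linkCode[strsplit(x$linkages, "")[[1L]]]),
        loci = lapply(x$loci, as.integer))
}

#' Write a design as versioned JSON
#'
#' One JSON document holding strands (bases, sugar and linkage strings,
#' loci), edges (paired position vectors), hinges and the gapmer location;
#' byte-stable for fixed input.
#'
#' @param design a [TDNDesign-class].
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeDesignJSON <- function(design, file) {
    doc <- list(
        schema = "gapmerTDN-design",
        version = .DESIGN_SCHEMA_VERSION,
        strands = lapply(designStrands(design), .strandToList),
        edges = lapply(designEdges(design), function(e)
            list(strandA = e@strandA, strandB = e@strandB,
                 posA = e@posA, posB = e@posB)),
        hinges = design@hinges,
        gapmerEdge = design@gapmerEdge,
        gapmerStrand = design@gapmerStrand,
        rnaStrand = design@rnaStrand)
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), file)
    invisible(file)
}

#' Read a design JSON written by [writeDesignJSON()]
#'
#' @param file path.
#' @return a [TDNDesign-class].
#' @export
readDesignJSON <- function(file) {
    doc <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    if (!identical(doc$schema, "gapmerTDN-design"))
        stop("not a design JSON document")
    strands <- lapply(doc$strands, .strandFromList)
    names(strands) <- vapply(strands, strandName, character(1))
    edges <- lapply(doc$edges, function(e)
        new("DuplexMap", strandA = e$strandA, strandB = e$strandB,
            posA = as.integer(e$posA), posB = as.integer(e$posB)))
    hinges <- lapply(doc$hinges, as.integer)
    new("TDNDesign", strands = strands, edges = edges, hinges = hinges,
        gapmerEdge = doc$gapmerEdge, gapmerStrand = doc$gapmerStrand,
        rnaStrand = doc$rnaStrand)
}
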