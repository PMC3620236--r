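# Data model, file I/O, haplogroup collapsing and trio validation.

#' Normalise haplotype labels to ASCII
#'
#' Published HLA tables mix typographic glyphs into allele names; input is
#' mapped to a single ASCII form so labels compare reliably: the ratio
#' colon (U+2236) becomes \code{":"}, en/em dashes become \code{"-"}, and
#' surrounding whitespace is dropped.
#'
#' @param x character vector of labels.
#' @return Normalised character vector.
#' @export
normalizeHaplotypeLabel <- function(x) {
    x <- gsub("∶", ":", x)
    x <- gsub("–|—", "-", x)
    trimws(x)
}

#' Canonical unordered genotype label
#'
#' Genotypes are unordered pairs of haplotypes; \code{"A/B"} and
#' \code{"B/A"} name the same genotype.  The canonical form sorts the two
#' haplotype labels (C-locale radix order) and joins them with \code{"/"}.
#'
#' @param x character vector of \code{"hapA/hapB"} labels.
#' @return Canonicalised labels.
#' @export
canonicalGenotype <- function(x) {
    x <- normalizeHaplotypeLabel(x)
    vapply(strsplit(x, "/", fixed = TRUE), function(p) {
        if (length(p) != 2L)
            stop("genotype label is not a 'hapA/hapB' pair: ",
                 paste(p, collapse = "/"))
        paste(sort(trimws(p), method = "radix"), collapse = "/")
    }, character(1))
}

#' Read a haplotype or genotype count table
#'
#' Reads a TSV with header columns \code{label}, \code{case_count},
#' \code{control_count}.  Cohort totals come either from a comment line
#' \code{#totals <case_total> <control_total>} inside the file or from the
#' \code{caseTotal}/\code{controlTotal} arguments (arguments win).
#'
#' @param path path to the TSV file.
#' @param kind \code{"haplotype"} (counts are chromosomes) or
#'   \code{"genotype"} (counts are individuals; labels are
#'   \code{"hapA/hapB"} pairs).
#' @param caseTotal,controlTotal optional cohort totals overriding the
#'   \code{#totals} line.
#' @return A \code{\link{HaplotypeCounts}} or \code{\link{GenotypeCounts}}.
#' @examples
#' tab <- readCountTable(hlaFixture("haplotypes"), "haplotype")
#' tab
#' @export
readCountTable <- function(path, kind = c("haplotype", "genotype"),
                           caseTotal = NULL, controlTotal = NULL) {
    kind <- match.arg(kind)
    lines <- readLines(path, encoding = "UTF-8")
    totline <- grep("^#totals\\b", lines)
    if (length(totline) && (is.null(caseTotal) || is.null(controlTotal))) {
        tot <- strsplit(sub("^#totals[ \t]+", "", lines[totline[1]]),
                        "[ \t]+")[[1]]
        if (length(tot) < 2L)
            stop("malformed #totals line (line ", totline[1], ") in ", path)
        if (is.null(caseTotal)) caseTotal <- as.integer(tot[1])
        if (is.null(controlTotal)) controlTotal <- as.integer(tot[2])
    }
    if (is.null(caseTotal) || is.null(controlTotal))
        stop("missing totals: supply caseTotal/controlTotal or a #totals line")
    body <- lines[!startsWith(lines, "#")]
    body <- body[nzchar(trimws(body))]
    if (length(body) < 2L)
        stop("no rows in ", path)
    df <- read.delim(text = paste(body, collapse = "\n"),
                     stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("label", "case_count", "control_count")
    if (!all(need %in% names(df)))
        stop("expected columns ", paste(need, collapse = ", "), " in ", path)
    for (col in c("case_count", "control_count")) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
        if (length(bad))
            stop("non-numeric ", col, " at data line ", bad[1], " of ", path)
        if (any(df[[col]] < 0))
            stop("negative ", col, " at data line ",
                 which(df[[col]] < 0)[1], " of ", path)
    }
    maker <- if (kind == "haplotype") HaplotypeCounts else GenotypeCounts
    maker(df$label, df$case_count, df$control_count, caseTotal, controlTotal)
}

#' Write a count table as canonical TSV
#'
#' Inverse of \code{\link{readCountTable}}: a \code{#totals} comment line
#' followed by the three-column table.  Reading the written file back
#' reproduces the object (and re-writing reproduces the file byte for
#' byte).
#'
#' @param x a count table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(x, path) {
    stopifnot(is(x, "CountTable"))
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(sprintf("#totals\t%d\t%d", x@caseTotal, x@controlTotal),
                 "label\tcase_count\tcontrol_count",
                 sprintf("%s\t%d\t%d", x@label, x@caseCount, x@controlCount)),
               con)
    invisible(path)
}

#' Read a haplogroup grouping map
#'
#' Two-column TSV \code{fine_label <TAB> group_label} (header optional,
#' detected by the names \code{fine_label}/\code{group_label}).
#'
#' @param path path to the TSV file.
#' @return Named character vector mapping fine labels to group labels.
#' @export
readGroupingMap <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("grouping map needs two columns in ", path)
    if (identical(tolower(df[1, 1]), "fine_label"))
        df <- df[-1, , drop = FALSE]
    setNames(normalizeHaplotypeLabel(df[[2]]),
             normalizeHaplotypeLabel(df[[1]]))
}

#' @rdname collapseHaplogroups
setMethod("collapseHaplogroups", "HaplotypeCounts", function(x, map) {
    if (is.data.frame(map))
        map <- setNames(normalizeHaplotypeLabel(map[[2]]),
                        normalizeHaplotypeLabel(map[[1]]))
    hit <- x@label %in% names(map)
    group <- x@label
    group[hit] <- unname(map[x@label[hit]])
    keep <- !duplicated(group)
    HaplotypeCounts(group[keep],
                    as.vector(rowsum(x@caseCount, group)[unique(group), ]),
                    as.vector(rowsum(x@controlCount, group)[unique(group), ]),
                    x@caseTotal, x@controlTotal)
})

#' @rdname filterByFrequency
setMethod("filterByFrequency", "CountTable", function(x, threshold = 0.01) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold <= 0 || threshold >= 1)
        stop("threshold must be a proportion strictly inside (0, 1)")
    keep <- x@caseCount / x@caseTotal >= threshold |
            x@controlCount / x@controlTotal >= threshold
    initialize(x, label = x@label[keep], caseCount = x@caseCount[keep],
               controlCount = x@controlCount[keep])
})

#' Read phased trio families from a PED-like TSV
#'
#' Columns \code{family_id}, \code{member} (\code{F}, \code{M} or
#' \code{C}), \code{hap1}, \code{hap2}, \code{status} (2 affected,
#' 1 unaffected, 0 unknown).  Haplotypes must already be phased; the
#' package validates consistency but never infers phase.
#'
#' @param path path to the TSV file (header required).
#' @return A \code{\link{TrioSet}}.
#' @export
readTrios <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("family_id", "member", "hap1", "hap2", "status")
    if (!all(need %in% names(df)))
        stop("expected columns ", paste(need, collapse = ", "), " in ", path)
    TrioSet(df$family_id, df$member, df$hap1, df$hap2, df$status)
}

#' @rdname readTrios
#' @param x a \code{TrioSet}.
#' @export
writeTrios <- function(x, path) {
    stopifnot(is(x, "TrioSet"))
    ped <- x@ped
    names(ped)[names(ped) == "family"] <- "family_id"
    write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.familySplit <- function(trios) split(trios@ped, trios@ped$family)

.childConsistent <- function(child, father, mother) {
    (child[1] %in% father && child[2] %in% mother) ||
    (child[2] %in% father && child[1] %in% mother)
}

#' Validate phased trio families
#'
#' Checks every child for Mendelian consistency (one haplotype matching a
#' paternal and the other a maternal haplotype) and flags intercross
#' families — both parents heterozygous for the same pair of haplotypes —
#' whose phase assignment is uninformative.  The validator only flags;
#' ambiguous families are never imputed or repaired.
#'
#' @param trios a \code{\link{TrioSet}}.
#' @return A data frame with one row per family: \code{family},
#'   \code{n_children}, \code{mendelian_consistent}, \code{intercross},
#'   \code{note}.
#' @export
validateTrios <- function(trios) {
    stopifnot(is(trios, "TrioSet"))
    fams <- .familySplit(trios)
    out <- lapply(fams, function(fam) {
        f <- unlist(fam[fam$member == "F", c("hap1", "hap2")], use.names = FALSE)
        m <- unlist(fam[fam$member == "M", c("hap1", "hap2")], use.names = FALSE)
        kids <- fam[fam$member == "C", , drop = FALSE]
        ok <- vapply(seq_len(nrow(kids)), function(i)
            .childConsistent(c(kids$hap1[i], kids$hap2[i]), f, m), logical(1))
        inter <- f[1] != f[2] && m[1] != m[2] && setequal(f, m)
        data.frame(family = fam$family[1], n_children = nrow(kids),
                   mendelian_consistent = all(ok), intercross = inter,
                   note = if (all(ok)) {
                       if (inter) "intercross (uninformative)" else ""
                   } else paste("inconsistent child:",
                                paste(which(!ok), collapse = ",")),
                   stringsAsFactors = FALSE)
    })
    ans <- do.call(rbind, out)
    rownames(ans) <- NULL
    ans
}

## ---- accessors, coercion, show -------------------------------------------

#' @rdname accessors
setMethod("countLabels", "CountTable", function(x, ...) x@label)
#' @rdname accessors
setMethod("caseCounts", "CountTable", function(x, ...)
    setNames(x@caseCount, x@label))
#' @rdname accessors
setMethod("controlCounts", "CountTable", function(x, ...)
    setNames(x@controlCount, x@label))
#' @rdname accessors
setMethod("caseTotal", "CountTable", function(x, ...) x@caseTotal)
#' @rdname accessors
setMethod("controlTotal", "CountTable", function(x, ...) x@controlTotal)
#' @rdname accessors
setMethod("pedigree", "TrioSet", function(x, ...) x@ped)
#' @rdname accessors
setMethod("transmitted", "TransmissionTable", function(x, ...)
    setNames(x@transmitted, x@label))
#' @rdname accessors
setMethod("notTransmitted", "TransmissionTable", function(x, ...)
    setNames(x@notTransmitted, x@label))
#' @rdname accessors
setMethod("nInformative", "TransmissionTable", function(x, ...)
    sum(x@transmitted))
#' @rdname accessors
setMethod("countLabels", "TransmissionTable", function(x, ...) x@label)

#' @export
setMethod("length", "CountTable", function(x) length(x@label))

#' @export
setMethod("as.data.frame", "CountTable",
    function(x, row.names = NULL, optional = FALSE, ...)
        data.frame(label = x@label, case_count = x@caseCount,
                   control_count = x@controlCount, stringsAsFactors = FALSE))

#' @export
setMethod("as.data.frame", "TransmissionTable",
    function(x, row.names = NULL, optional = FALSE, ...)
        data.frame(stratum = x@stratum, label = x@label,
                   transmitted = x@transmitted,
                   not_transmitted = x@notTransmitted,
                   stringsAsFactors = FALSE))

setMethod("show", "CountTable", function(object) {
    unit <- if (is(object, "HaplotypeCounts")) "chromosomes" else "individuals"
    cat(class(object), "with", length(object@label), "rows;",
        object@caseTotal, "case and", object@controlTotal,
        paste0("control ", unit, "\n"))
    print(utils::head(as.data.frame(object), 8), row.names = FALSE)
    if (length(object@label) > 8) cat("...", length(object@label) - 8,
                                      "more rows\n")
})

setMethod("show", "TrioSet", function(object) {
    ped <- object@ped
    cat("TrioSet with", length(unique(ped$family)), "families (",
        sum(ped$member == "C"), "children )\n")
})

setMethod("show", "TransmissionTable", function(object) {
    cat("TransmissionTable [", object@stratum, "]:",
        nInformative(object), "informative parents,",
        length(object@label), "haplotypes\n")
})
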