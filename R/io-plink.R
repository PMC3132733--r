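#' Reading and writing the pipeline's file formats
#'
#' PLINK text PED/MAP genotypes (missing allele `"0"`, phenotype
#' 1 = control / 2 = case), tab-separated covariate and SNP-to-gene
#' tables, and GMT gene-set files.
#'
#' @name io
NULL

#' Read PLINK text PED/MAP genotypes
#'
#' Parses a PED/MAP pair and recodes alleles to minor-allele dosage using
#' allele frequencies in the total sample; on a frequency tie the
#' lexicographically smaller allele is taken as minor. The missing allele
#' code `"0"` yields a missing dosage. Phenotype column 1 maps to control
#' (0), 2 to case (1), anything else to `NA`; PED sex 1 = male -> 1,
#' 2 = female -> 0.
#'
#' @param pedPath path to the PED file.
#' @param mapPath path to the MAP file (columns: chr, snp id, genetic
#'   distance, bp position).
#' @return A [GenotypeExperiment] with `status` and `sex` in `colData`
#'   and `chr`, `pos`, `alleleMinor`, `alleleMajor` in `rowData`.
#' @export
readPedMap <- function(pedPath, mapPath) {
    if (!file.exists(pedPath)) stop("PED file not found: ", pedPath)
    if (!file.exists(mapPath)) stop("MAP file not found: ", mapPath)
    map <- data.table::fread(mapPath, header = FALSE, sep = "\t",
                             colClasses = "character",
                             data.table = FALSE)
    if (ncol(map) == 1L)       # whitespace-delimited fallback
        map <- utils::read.table(mapPath, header = FALSE,
                                 colClasses = "character")
    if (ncol(map) < 4L)
        stop("MAP file needs 4 columns (chr, snp, cM, bp)")
    snpIds <- map[[2L]]
    m <- length(snpIds)
    if (anyDuplicated(snpIds))
        stop("duplicate SNP id in MAP file: ",
             snpIds[anyDuplicated(snpIds)])

    pedLines <- readLines(pedPath)
    pedLines <- pedLines[nzchar(trimws(pedLines))]
    tok <- strsplit(trimws(pedLines), "[ \t]+")
    want <- 6L + 2L * m
    bad <- which(lengths(tok) != want)
    if (length(bad))
        stop("PED line ", bad[1L], " has ", lengths(tok)[bad[1L]],
             " fields, expected ", want)
    n <- length(tok)
    ped <- matrix(unlist(tok), nrow = n, byrow = TRUE)
    iid <- ped[, 2L]
    subjId <- paste(ped[, 1L], ped[, 2L], sep = ":")
    dupRow <- anyDuplicated(subjId)
    if (dupRow)
        stop("duplicate subject id at PED line ", dupRow, ": ",
             subjId[dupRow])
    sex <- ifelse(ped[, 5L] == "1", 1L, ifelse(ped[, 5L] == "2", 0L,
                                               NA_integer_))
    status <- ifelse(ped[, 6L] == "2", 1L, ifelse(ped[, 6L] == "1", 0L,
                                                  NA_integer_))

    d <- matrix(NA_real_, nrow = m, ncol = n,
                dimnames = list(snpIds, iid))
    alleleMinor <- alleleMajor <- rep(NA_character_, m)
    for (j in seq_len(m)) {
        a1 <- ped[, 5L + 2L * j]
        a2 <- ped[, 6L + 2L * j]
        missing <- a1 == "0" | a2 == "0"
        obs <- c(a1[!missing], a2[!missing])
        alleles <- sort(unique(obs))
        if (length(alleles) > 2L)
            stop("SNP ", snpIds[j], " has ", length(alleles),
                 " observed alleles: ", paste(alleles, collapse = "/"))
        if (length(alleles) == 0L) next           # fully missing SNP
        if (length(alleles) == 1L) {
            alleleMajor[j] <- alleles
            d[j, !missing] <- 0
            next
        }
        counts <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
        minor <- if (counts[1L] <= counts[2L]) alleles[1L] else alleles[2L]
        alleleMinor[j] <- minor
        alleleMajor[j] <- setdiff(alleles, minor)
        d[j, ] <- (a1 == minor) + (a2 == minor)
        d[j, missing] <- NA_real_
    }
    snpInfo <- S4Vectors::DataFrame(
        chr = map[[1L]], pos = as.integer(map[[4L]]),
        alleleMinor = alleleMinor, alleleMajor = alleleMajor)
    subjectInfo <- S4Vectors::DataFrame(fid = ped[, 1L], sex = sex,
                                        status = status, row.names = iid)
    GenotypeExperiment(d, snpInfo = snpInfo, subjectInfo = subjectInfo)
}

#' Write PLINK text PED/MAP genotypes
#'
#' Inverse of [readPedMap()]. Dosage 2 writes two minor alleles, 1 writes
#' minor then major, 0 two major alleles, `NA` writes `"0 0"`. Phenotype
#' is written 1 = control / 2 = case (0 when missing); sex 1 = male /
#' 2 = female (0 when missing). Allele letters and map coordinates come
#' from `rowData` (`alleleMinor`/`alleleMajor`, defaulting to `"A"`/`"B"`).
#'
#' @param ge a [GenotypeExperiment].
#' @param pedPath,mapPath output paths.
#' @return Invisibly, the two paths.
#' @export
writePedMap <- function(ge, pedPath, mapPath) {
    stopifnot(methods::is(ge, "GenotypeExperiment"))
    d <- dosage(ge)
    rd <- SummarizedExperiment::rowData(ge)
    cd <- SummarizedExperiment::colData(ge)
    m <- nrow(d); n <- ncol(d)
    minor <- if ("alleleMinor" %in% colnames(rd))
        as.character(rd$alleleMinor) else rep("A", m)
    major <- if ("alleleMajor" %in% colnames(rd))
        as.character(rd$alleleMajor) else rep("B", m)
    minor[is.na(minor)] <- "A"; major[is.na(major)] <- "B"
    chr <- if ("chr" %in% colnames(rd)) as.character(rd$chr)
        else rep("1", m)
    pos <- if ("pos" %in% colnames(rd)) as.integer(rd$pos)
        else seq_len(m) * 1000L
    writeLines(paste(chr, rownames(d), 0L, pos, sep = "\t"), mapPath)

    sexPed <- rep(0L, n)
    if ("sex" %in% colnames(cd))
        sexPed <- ifelse(is.na(cd$sex), 0L, ifelse(cd$sex == 1, 1L, 2L))
    phenoPed <- rep(0L, n)
    st <- caseStatus(ge)
    if (!is.null(st))
        phenoPed <- ifelse(is.na(st), 0L, st + 1L)
    fid <- if ("fid" %in% colnames(cd)) as.character(cd$fid)
        else colnames(d)

    lines <- vapply(seq_len(n), function(i) {
        g <- d[, i]
        a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, minor, major))
        a2 <- ifelse(is.na(g), "0", ifelse(g == 2, minor, major))
        paste(c(fid[i], colnames(d)[i], "0", "0", sexPed[i], phenoPed[i],
                as.vector(rbind(a1, a2))), collapse = "\t")
    }, character(1))
    writeLines(lines, pedPath)
    invisible(c(ped = pedPath, map = mapPath))
}

#' Read a GMT gene-set file
#'
#' Each line holds a set name, a description, and one or more member gene
#' ids, tab-separated. Duplicate members within a set are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions are kept in the
#'   `"description"` attribute of each element.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(stats::setNames(list(), character(0)))
    sets <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("GMT line ", i, ": need name, description and >= 1 member")
        if (!nzchar(trimws(f[1L])))
            stop("GMT line ", i, ": blank set name")
        members <- f[-(1:2)]
        members <- members[nzchar(members)]
        if (!length(members))
            stop("GMT line ", i, ": set '", f[1L], "' has no members")
        if (anyDuplicated(members)) {
            warning("GMT line ", i, ": duplicated members in set '",
                    f[1L], "' de-duplicated")
            members <- unique(members)
        }
        structure(members, description = f[2L])
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
        USE.NAMES = FALSE)
    if (anyDuplicated(names(sets)))
        stop("duplicate set name in GMT file: ",
             names(sets)[anyDuplicated(names(sets))])
    sets
}

#' Write gene sets in GMT format
#'
#' @param geneSets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of descriptions.
#' @return Invisibly, the path.
#' @export
writeGmt <- function(geneSets, path, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- rep("na", length(geneSets))
    writeLines(vapply(seq_along(geneSets), function(i)
        paste(c(names(geneSets)[i], descriptions[i], geneSets[[i]]),
              collapse = "\t"), character(1)), path)
    invisible(path)
}

#' Read a SNP-to-gene annotation table
#'
#' Two tab-separated columns: SNP id, gene id (a header line `snp<TAB>gene`
#' is tolerated). Many SNPs may map to one gene; a SNP may appear once.
#'
#' @param path TSV path.
#' @return Named character vector, SNP id -> gene id.
#' @export
readSnpGeneMap <- function(path) {
    if (!file.exists(path)) stop("SNP-gene map not found: ", path)
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             colClasses = "character")
    if (ncol(tab) < 2L) stop("SNP-gene map needs 2 tab-separated columns")
    if (nrow(tab) && tolower(tab[1L, 1L]) %in% c("snp", "snp_id", "snpid"))
        tab <- tab[-1L, , drop = FALSE]
    if (anyDuplicated(tab[[1L]]))
        stop("SNP mapped to more than one gene: ",
             tab[[1L]][anyDuplicated(tab[[1L]])])
    stats::setNames(tab[[2L]], tab[[1L]])
}

#' @rdname readSnpGeneMap
#' @param snpGeneMap named character vector to write.
#' @export
writeSnpGeneMap <- function(snpGeneMap, path) {
    utils::write.table(
        data.frame(snp = names(snpGeneMap), gene = unname(snpGeneMap)),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Read a covariate table
#'
#' Tab-separated with header `FID IID AGE SEX` (sex coded 0 = female /
#' 1 = male).
#'
#' @param path TSV path.
#' @return `DataFrame` with rownames = IID and columns `fid`, `age`,
#'   `sex`.
#' @export
readCovariates <- function(path) {
    if (!file.exists(path)) stop("covariate file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    need <- c("fid", "iid", "age", "sex")
    if (!all(need %in% names(tab)))
        stop("covariate file needs columns FID, IID, AGE, SEX")
    if (anyDuplicated(tab$iid))
        stop("duplicate IID in covariate file: ",
             tab$iid[anyDuplicated(tab$iid)])
    S4Vectors::DataFrame(fid = tab$fid, age = as.numeric(tab$age),
                         sex = as.integer(tab$sex), row.names = tab$iid)
}

#' @rdname readCovariates
#' @param ge a [GenotypeExperiment] whose `colData` supplies `age`/`sex`.
#' @export
writeCovariates <- function(ge, path) {
    cd <- SummarizedExperiment::colData(ge)
    fid <- if ("fid" %in% colnames(cd)) as.character(cd$fid)
        else rownames(cd)
    utils::write.table(
        data.frame(FID = fid, IID = rownames(cd),
                   AGE = if ("age" %in% colnames(cd)) cd$age else NA,
                   SEX = if ("sex" %in% colnames(cd)) cd$sex else NA),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Attach covariates read from file to a genotype object
#'
#' Matches subjects by id and merges `age`/`sex` into `colData`.
#'
#' @param ge a [GenotypeExperiment].
#' @param covariates `DataFrame` from [readCovariates()].
#' @return The updated [GenotypeExperiment].
#' @export
attachCovariates <- function(ge, covariates) {
    ids <- colnames(dosage(ge))
    if (!all(ids %in% rownames(covariates)))
        stop("covariate table is missing subjects: ",
             paste(utils::head(setdiff(ids, rownames(covariates)), 5L),
                   collapse = ", "))
    cd <- SummarizedExperiment::colData(ge)
    cd$age <- covariates[ids, "age"]
    cd$sex <- covariates[ids, "sex"]
    SummarizedExperiment::colData(ge) <- cd
    ge
}

#' Write a complete synthetic cohort to disk
#'
#' Emits the PLINK PED/MAP pair, the covariate TSV, the SNP-to-gene TSV
#' and the GMT file for a simulated study, so the pipeline's real readers
#' can be exercised end to end.
#'
#' @param ge a [GenotypeExperiment] with phenotypes in `colData`.
#' @param truth an [AnnotationTruth].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"cohort"`).
#' @return Invisibly, a named vector of the five paths.
#' @export
writeCohort <- function(ge, truth, dir, prefix = "cohort") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        ped = file.path(dir, paste0(prefix, ".ped")),
        map = file.path(dir, paste0(prefix, ".map")),
        covariates = file.path(dir, paste0(prefix, ".cov.tsv")),
        snp2gene = file.path(dir, paste0(prefix, ".snp2gene.tsv")),
        gmt = file.path(dir, paste0(prefix, ".gmt")))
    writePedMap(ge, paths["ped"], paths["map"])
    writeCovariates(ge, paths["covariates"])
    writeSnpGeneMap(truth@snpGeneMap, paths["snp2gene"])
    writeGmt(truth@geneSets, paths["gmt"])
    invisible(paths)
}
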