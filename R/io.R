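#' Write a trio cohort as PLINK text .ped/.map
#'
#' One family per trio with three rows (father, mother, child). `.ped` columns
#' are `FID IID PAT MAT SEX PHENO` followed by two allele characters per SNP
#' (`0 0` = missing); `.map` columns are `CHR SNP CM BP`. Children of
#' ascertained cohorts get phenotype 2 (affected), parents 1.
#'
#' @param cohort a `trio_cohort`.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(cohort, prefix) {
  stop_if_not_cohort(cohort)
  snps <- cohort$snps
  geno_strings <- function(G) {
    # dosage -> "x y" allele pairs, minor = a1, major = a2
    out <- matrix("", nrow(G), ncol(G))
    for (j in seq_len(ncol(G))) {
      al <- c(paste(snps$a2[j], snps$a2[j]), paste(snps$a1[j], snps$a2[j]),
              paste(snps$a1[j], snps$a1[j]))
      g <- G[, j]
      out[, j] <- ifelse(is.na(g), "0 0", al[g + 1L])
    }
    out
  }
  n <- cohort$n_trios
  fid <- paste0("FAM", seq_len(n))
  pheno_child <- ifelse(is.na(cohort$affected) | cohort$affected, 2L, 1L)
  rows <- rbind(
    cbind(fid, paste0(fid, "_F"), "0", "0", "1", "1",
          geno_strings(cohort$father)),
    cbind(fid, paste0(fid, "_M"), "0", "0", "2", "1",
          geno_strings(cohort$mother)),
    cbind(fid, paste0(fid, "_C"), paste0(fid, "_F"), paste0(fid, "_M"),
          as.character(cohort$sex), as.character(pheno_child),
          geno_strings(cohort$child))
  )
  ped <- paste0(prefix, ".ped"); map <- paste0(prefix, ".map")
  utils::write.table(rows, ped, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  utils::write.table(
    data.frame(snps$chr, snps$snp_id, 0, snps$pos),
    map, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " "
  )
  invisible(c(ped = ped, map = map))
}

#' Read PLINK text .ped/.map into a trio cohort
#'
#' Alleles are recoded to minor-allele dosage with the minor allele defined by
#' founder frequency in the loaded cohort (ties at 0.5 broken by taking the
#' lexicographically smaller allele label as minor); allele `"0"` means
#' missing. Trios are linked through `FID`/`PAT`/`MAT`: each individual whose
#' two parents are present in the same family becomes a child row.
#'
#' @param ped_path,map_path file paths.
#' @return a `trio_cohort` (with `snps$maf` set to the founder MAF).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("no such file: ", map_path, call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chr", "snp_id", "cm", "pos"),
                           stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  bad <- which(lengths(toks) != want)
  if (length(bad))
    stop("ragged .ped row(s) at line(s) ", paste(utils::head(bad, 5),
         collapse = ", "), ": expected ", want, " fields", call. = FALSE)
  tok <- do.call(rbind, toks)
  meta <- tok[, 1:6, drop = FALSE]
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  n_ind <- nrow(tok)

  # identify trios: child rows have both parents in the same family
  key <- function(f, i) paste(f, i, sep = "\r")
  ids <- key(meta[, 1], meta[, 2])
  has_f <- match(key(meta[, 1], meta[, 3]), ids)
  has_m <- match(key(meta[, 1], meta[, 4]), ids)
  named_parent <- meta[, 3] != "0" | meta[, 4] != "0"
  unknown <- named_parent & (meta[, 3] != "0" & is.na(has_f) |
                               meta[, 4] != "0" & is.na(has_m))
  if (any(unknown))
    stop("unknown parent ID(s) for individual(s): ",
         paste(utils::head(meta[unknown, 2], 5), collapse = ", "),
         call. = FALSE)
  child_rows <- which(!is.na(has_f) & !is.na(has_m))
  if (!length(child_rows)) stop("no complete trios found", call. = FALSE)

  # minor allele by founder frequency
  founder_rows <- setdiff(seq_len(n_ind), child_rows)
  dosage <- matrix(NA_integer_, n_ind, m)
  minor <- major <- character(m)
  maf <- numeric(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- setdiff(unique(al), "0")
    if (length(obs) > 2)
      stop("SNP ", map$snp_id[j], " has more than two alleles: ",
           paste(obs, collapse = "/"), call. = FALSE)
    if (length(obs) == 0) obs <- c("A", "B")
    if (length(obs) == 1) obs <- c(obs, if (obs == "A") "B" else "A")
    fal <- c(a1[founder_rows, j], a2[founder_rows, j])
    fal <- fal[fal != "0"]
    f1 <- if (length(fal)) mean(fal == obs[1]) else 0.5
    obs <- obs[order(c(f1, 1 - f1), obs)]  # minor first; tie -> lexicographic
    minor[j] <- obs[1]; major[j] <- obs[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
    d[miss] <- NA_integer_
    dosage[, j] <- d
    fd <- d[founder_rows]
    maf[j] <- if (all(is.na(fd))) NA_real_ else
      sum(fd, na.rm = TRUE) / (2 * sum(!is.na(fd)))
  }
  snps <- data.frame(snp_id = map$snp_id, chr = as.integer(map$chr),
                     pos = as.integer(map$pos), a1 = minor, a2 = major,
                     maf = maf, stringsAsFactors = FALSE)
  new_trio_cohort(
    father = dosage[has_f[child_rows], , drop = FALSE],
    mother = dosage[has_m[child_rows], , drop = FALSE],
    child = dosage[child_rows, , drop = FALSE],
    snps = snps,
    sex = suppressWarnings(as.integer(meta[child_rows, 5])),
    affected = meta[child_rows, 6] == "2"
  )
}

#' Write a tab-separated results table
#'
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table (TSV)
#'
#' Expects at least `sample_id`, `group`, `trait`; any `cov*` columns are
#' treated as covariates downstream.
#'
#' @param path TSV path with a header row.
#' @return data.frame.
#' @export
read_pheno <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "trait")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ph
}
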