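#' Call variant presence per sample
#'
#' Binarizes the harmonized VAF grid: a variant is present in a sample
#' when its observed VAF is strictly greater than \code{presence_vaf}
#' (default 10%, the threshold at which serial-sample mutation sets are
#' compared). Missing cells propagate as \code{NA} (unknown), never as
#' absent.
#'
#' @param vm a [VafMatrix-class].
#' @param presence_vaf strict lower VAF bound for presence.
#' @return logical matrix, variants x samples, with \code{NA} for
#'   unobserved cells.
#' @export
callPresence <- function(vm, presence_vaf = 0.10) {
    v <- SummarizedExperiment::assay(vm, "vaf")
    pres <- v > presence_vaf
    pres
}

## consensus profile of a set of presence rows: majority vote per sample
consensusProfile <- function(mat) {
    apply(mat, 2, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) FALSE else mean(col) >= 0.5
    })
}

#' Partition variants into mutually exclusive subclone sets
#'
#' Groups variants by their binary presence profile across the serial
#' samples. Variants present in every sample are labeled \code{"shared"}
#' (carried by all subclones, i.e. acquired before divergence). The
#' remaining profiles are clustered with single-link merging at Hamming
#' distance \code{<= merge_hamming} (default 1, tolerating one noisy
#' cell); clusters of at least \code{min_clone_size} variants become
#' clones, labeled \code{"A"}, \code{"B"}, ... in order of first
#' chronological appearance; smaller clusters are \code{"unassigned"}.
#'
#' The exclusivity index operationalizes "mutually exclusive" mutation
#' sets: the fraction of clone-assigned variants whose observed presence
#' touches the characteristic samples of only their own clone. It is 1
#' when clone-defining sets never co-occur.
#'
#' @param presence logical matrix from [callPresence()], or a
#'   [VafMatrix-class] (then \code{presence_vaf} is applied first).
#' @param min_clone_size minimum variants for a cluster to be a clone.
#' @param merge_hamming maximum Hamming distance for profile merging.
#' @param presence_vaf used only when \code{presence} is a VafMatrix.
#' @return a [ClonePartition-class].
#' @export
partitionClones <- function(presence, min_clone_size = 2,
                            merge_hamming = 1, presence_vaf = 0.10) {
    if (methods::is(presence, "VafMatrix"))
        presence <- callPresence(presence, presence_vaf)
    stopIfNot1(is.matrix(presence), "presence must be a logical matrix")
    stopIfNot1(ncol(presence) >= 2,
               "clone partition undefined for a single sample")
    nS <- ncol(presence)
    labs <- colnames(presence)
    if (is.null(labs)) labs <- paste0("S", seq_len(nS))
    keys <- rownames(presence)
    if (is.null(keys)) keys <- as.character(seq_len(nrow(presence)))

    obs <- presence
    obs[is.na(obs)] <- FALSE   # unknown counts as not-present for grouping
    clone <- rep(NA_character_, nrow(presence))

    shared <- rowSums(obs) == nS
    clone[shared] <- "shared"
    none <- rowSums(obs) == 0
    clone[none] <- "unassigned"

    idx <- which(is.na(clone))
    cloneProfiles <- NULL
    presFrac <- NULL
    if (length(idx)) {
        prof <- apply(obs[idx, , drop = FALSE], 1, paste, collapse = "")
        groups <- split(idx, prof)
        groups <- groups[order(-lengths(groups))]
        reps <- list()   # cluster representative profiles
        members <- list()
        for (g in seq_along(groups)) {
            p <- obs[groups[[g]][1], ]
            placed <- FALSE
            for (ci in seq_along(reps)) {
                if (sum(p != reps[[ci]]) <= merge_hamming) {
                    members[[ci]] <- c(members[[ci]], groups[[g]])
                    placed <- TRUE
                    break
                }
            }
            if (!placed) {
                reps[[length(reps) + 1]] <- p
                members[[length(members) + 1]] <- groups[[g]]
            }
        }
        isClone <- lengths(members) >= min_clone_size
        ## clone order: first sample of presence in the consensus profile,
        ## then size (larger first) for deterministic labeling
        cons <- lapply(members, function(m)
            consensusProfile(obs[m, , drop = FALSE]))
        firstOn <- vapply(cons, function(p)
            if (any(p)) which(p)[1] else nS + 1L, 0L)
        ord <- order(!isClone, firstOn, -lengths(members))
        lab <- character(length(members))
        nextClone <- 1L
        for (ci in ord) {
            if (isClone[ci]) {
                lab[ci] <- LETTERS[nextClone]
                nextClone <- nextClone + 1L
            } else lab[ci] <- "unassigned"
        }
        for (ci in seq_along(members))
            clone[members[[ci]]] <- lab[ci]
        cloneNames <- sort(unique(lab[isClone]))
        if (length(cloneNames)) {
            cloneProfiles <- do.call(rbind, lapply(cloneNames, function(cn) {
                m <- unlist(members[lab == cn])
                consensusProfile(obs[m, , drop = FALSE])
            }))
            dimnames(cloneProfiles) <- list(cloneNames, labs)
        }
    }

    allClones <- if (is.null(cloneProfiles)) character() else
        rownames(cloneProfiles)
    trackNames <- c(allClones, if (any(clone == "shared")) "shared")
    if (length(trackNames)) {
        presFrac <- do.call(rbind, lapply(trackNames, function(cn) {
            m <- which(clone == cn)
            colMeans(obs[m, , drop = FALSE])
        }))
        dimnames(presFrac) <- list(trackNames, labs)
    } else {
        presFrac <- matrix(numeric(), 0, nS, dimnames = list(NULL, labs))
    }
    if (is.null(cloneProfiles))
        cloneProfiles <- matrix(logical(), 0, nS,
                                dimnames = list(NULL, labs))

    ## exclusivity: a clone-assigned variant violates exclusivity when its
    ## presence touches the characteristic samples of >= 2 clones
    ei <- NA_real_
    assigned <- which(clone %in% allClones)
    if (length(assigned) && nrow(cloneProfiles)) {
        nTouched <- vapply(assigned, function(i) {
            sum(vapply(rownames(cloneProfiles), function(cn)
                any(obs[i, ] & cloneProfiles[cn, ]), TRUE))
        }, 0L)
        ei <- 1 - sum(nTouched >= 2) / length(assigned)
    } else if (length(assigned)) {
        ei <- 1
    }

    assignment <- data.frame(
        key = keys,
        chrom = NA_character_, pos = NA_integer_,
        ref = NA_character_, alt = NA_character_, gene = NA_character_,
        clone = clone, stringsAsFactors = FALSE)
    parts <- strsplit(keys, ":", fixed = TRUE)
    if (all(lengths(parts) >= 4)) {
        assignment$chrom <- vapply(parts, `[`, "", 1)
        assignment$pos <- suppressWarnings(
            as.integer(vapply(parts, `[`, "", 2)))
        assignment$ref <- vapply(parts, `[`, "", 3)
        assignment$alt <- vapply(parts, `[`, "", 4)
    }
    methods::new("ClonePartition",
        assignment = assignment,
        profiles = cloneProfiles,
        presenceFraction = presFrac,
        exclusivityIndex = ei,
        sampleLabels = labs)
}

#' @describeIn ClonePartition-class clone labels in assignment order.
#' @param object,x a \code{ClonePartition}.
#' @export
setGeneric("cloneAssignment", function(x) standardGeneric("cloneAssignment"))

#' @rdname ClonePartition-class
#' @export
setMethod("cloneAssignment", "ClonePartition", function(x) x@assignment)

#' @rdname ClonePartition-class
#' @export
setGeneric("cloneSizes", function(x) standardGeneric("cloneSizes"))

#' @rdname ClonePartition-class
#' @export
setMethod("cloneSizes", "ClonePartition", function(x) {
    tab <- table(x@assignment$clone)
    sizes <- as.integer(tab)
    names(sizes) <- names(tab)
    sizes
})

#' @rdname ClonePartition-class
#' @export
setGeneric("exclusivityIndex", function(x) standardGeneric("exclusivityIndex"))

#' @rdname ClonePartition-class
#' @export
setMethod("exclusivityIndex", "ClonePartition",
          function(x) x@exclusivityIndex)

setMethod("show", "ClonePartition", function(object) {
    sz <- table(object@assignment$clone)
    cat("ClonePartition across", length(object@sampleLabels), "samples (",
        paste(object@sampleLabels, collapse = ", "), ")\n")
    cat("  variants:", nrow(object@assignment), "|",
        paste(sprintf("%s=%d", names(sz), as.integer(sz)), collapse = ", "),
        "\n")
    cat("  exclusivity index:",
        format(object@exclusivityIndex, digits = 3), "\n")
})

#' Detect clonal replacement between consecutive samples
#'
#' Scans adjacent time points for a switch of the dominant subclone: an
#' event \code{out -> in} is emitted between samples \code{i} and
#' \code{i+1} when clone \code{out}'s presence fraction falls below
#' \code{drop_factor} (default one half) of its level at sample \code{i}
#' while clone \code{in}'s presence fraction at \code{i+1} is positive and
#' at least that of \code{out}. A clone persisting across the whole series
#' yields no events.
#'
#' @param partition a [ClonePartition-class].
#' @param samples optional chronological sample order (defaults to the
#'   partition's); must be unique and match the partition labels.
#' @param drop_factor multiplicative drop defining a replacement.
#' @return data.frame: \code{clone_out}, \code{clone_in},
#'   \code{from_sample}, \code{to_sample}, \code{interval} (index of the
#'   earlier sample).
#' @export
detectReplacement <- function(partition, samples = NULL,
                              drop_factor = 0.5) {
    stopIfNot1(methods::is(partition, "ClonePartition"),
               "need a ClonePartition")
    labs <- partition@sampleLabels
    if (!is.null(samples)) {
        if (anyDuplicated(samples))
            stop("duplicate sample labels", call. = FALSE)
        if (!setequal(samples, labs))
            stop("sample labels do not match the partition", call. = FALSE)
        labs <- samples
    }
    pf <- partition@presenceFraction[, labs, drop = FALSE]
    clones <- setdiff(rownames(pf), "shared")
    out <- data.frame(clone_out = character(), clone_in = character(),
                      from_sample = character(), to_sample = character(),
                      interval = integer(), stringsAsFactors = FALSE)
    if (length(clones) < 2 || length(labs) < 2) return(out)
    for (i in seq_len(length(labs) - 1)) {
        for (co in clones) {
            dropped <- pf[co, i] > 0 &&
                pf[co, i + 1] < drop_factor * pf[co, i]
            if (!dropped) next
            for (ci in setdiff(clones, co)) {
                rose <- pf[ci, i + 1] > 0 &&
                    pf[ci, i + 1] >= pf[co, i + 1] &&
                    pf[ci, i + 1] >= pf[ci, i]
                if (rose) {
                    out <- rbind(out, data.frame(
                        clone_out = co, clone_in = ci,
                        from_sample = labs[i], to_sample = labs[i + 1],
                        interval = i, stringsAsFactors = FALSE))
                }
            }
        }
    }
    rownames(out) <- NULL
    out
}

#' Export a heat-map-ready presence/VAF matrix
#'
#' Orders variants by clone assignment (clones in label order, then
#' shared, then unassigned) and samples chronologically, the layout used
#' to display serial-sample VAF heat maps.
#'
#' @param vm a [VafMatrix-class].
#' @param partition matching [ClonePartition-class].
#' @return numeric VAF matrix reordered for display, with a
#'   \code{"clone"} attribute giving the row blocks.
#' @export
heatmapMatrix <- function(vm, partition) {
    asg <- partition@assignment
    lev <- c(sort(setdiff(unique(asg$clone), c("shared", "unassigned"))),
             "shared", "unassigned")
    ord <- order(match(asg$clone, lev))
    v <- SummarizedExperiment::assay(vm, "vaf")[asg$key[ord], ,
                                                drop = FALSE]
    attr(v, "clone") <- asg$clone[ord]
    v
}
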