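test_that("revcomp is a validated involution", {
  expect_equal(revcomp("ACGT"), "ACGT")  # palindrome
  expect_equal(revcomp("AAAC"), "GTTT")
  expect_error(revcomp("ACGN"), "A,C,G,T")
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
          collapse = ""), "")
  expect_equal(revcomp(revcomp(seqs)), seqs)
})

test_that("bidirectional tokenization slides both orientations", {
  tk <- tokenize_bikmer("ACGTA", k = 3)
  expect_equal(tk$forward, c("ACG", "CGT", "GTA"))
  expect_equal(tk$reverse, c("TAC", "ACG", "CGT"))  # revcomp = TACGT
  tk2 <- tokenize_bikmer("ACGTACG", k = 3, stride = 2)
  expect_equal(tk2$forward, c("ACG", "GTA", "ACG"))
  expect_error(tokenize_bikmer("AC", k = 3), "shorter than k")
})

test_that("tokenizing the reverse-complement swaps the token lists", {
  set.seed(5)
  for (i in 1:25) {
    len <- sample(10:60, 1)
    k <- sample(2:8, 1)
    stride <- sample(1:3, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    a <- tokenize_bikmer(s, k, stride)
    b <- tokenize_bikmer(revcomp(s), k, stride)
    expect_identical(b$forward, a$reverse)
    expect_identical(b$reverse, a$forward)
    n_expected <- floor((len - k) / stride) + 1
    expect_length(a$forward, n_expected)
    expect_length(a$reverse, n_expected)
  }
})

test_that("corpora contain two sentences per record with formula lengths", {
  ds <- toy_dataset()[1:3, ]
  corpus <- build_corpus(hftc_dataset(ds), k = 5, stride = 2)
  expect_length(corpus, 6L)
  lens <- floor((nchar(ds$sequence) - 5) / 2) + 1
  expect_equal(lengths(corpus), rep(lens, each = 2))
  # identical records yield pairwise identical sentences
  same <- hftc_dataset(data.frame(id = c("x", "y"),
                                  sequence = "ACGTACGTAC",
                                  kingdom = "F", phylum = "P", class = "C",
                                  order = "O", family = "Fa", genus = "G",
                                  species = "S"))
  cs <- build_corpus(same, k = 3)
  expect_identical(cs[[1]], cs[[3]])
  expect_identical(cs[[2]], cs[[4]])
})

test_that("skip-gram training is deterministic with full vocabulary control", {
  corpus <- list(c("ACG", "CGT", "GTA", "ACG", "CGT"),
                 c("TAC", "ACG", "CGT", "GTA", "TTT"))
  m1 <- train_embedding(corpus, N = 8, epochs = 3, seed = 3)
  expect_equal(nrow(m1$vectors), 5L)  # 5 distinct k-mers, min_count = 1
  expect_equal(ncol(m1$vectors), 8L)
  m2 <- train_embedding(corpus, N = 8, epochs = 3, seed = 3)
  expect_identical(m1$vectors, m2$vectors)
  m3 <- train_embedding(corpus, N = 8, epochs = 3, seed = 4)
  expect_false(identical(m1$vectors, m3$vectors))
  expect_error(train_embedding(list()), "empty corpus")
})

fake_model <- function(vectors, k) {
  structure(list(k = k, dim = ncol(vectors), vectors = vectors,
                 params = list()), class = "kmer_embedding")
}

test_that("sequence vectors are per-direction means over the vocabulary", {
  vecs <- rbind(ACG = c(1, 0), CGT = c(0, 1))
  m <- fake_model(vecs, 3L)
  sv <- embed_sequence(tokenize_bikmer("ACGT", 3), m)
  expect_equal(sv$values, c(0.5, 0.5, 0.5, 0.5))  # palindromic case
  expect_equal(sv$n_oov_forward, 0L)
  # all tokens OOV -> zero vector with counted drops
  sv2 <- embed_sequence(tokenize_bikmer("AAAA", 3), m)
  expect_equal(sv2$values, rep(0, 4))
  expect_equal(sv2$n_oov_forward, 2L)
  expect_equal(sv2$n_oov_reverse, 2L)
  # single-token sequence: concat of token vector and revcomp-token vector
  sv3 <- embed_sequence(tokenize_bikmer("ACG", 3), m)
  expect_equal(sv3$values, c(1, 0, 0, 1))  # revcomp(ACG) = CGT
  expect_error(embed_sequence(tokenize_bikmer("ACGT", 2), m), "match")
})

test_that("a constant vocabulary embeds every sequence to the same point", {
  all3 <- .codes_to_kmers_cpp(0:63, 3L)
  vecs <- matrix(rep(c(2, -1), each = 64), 64, 2,
                 dimnames = list(all3, NULL))
  m <- fake_model(vecs, 3L)
  s1 <- embed_sequence(tokenize_bikmer("ACGTACGTAA", 3), m)$values
  s2 <- embed_sequence(tokenize_bikmer("GGGCCCTTT", 3), m)$values
  expect_equal(s1, c(2, -1, 2, -1))
  expect_equal(s1, s2)
})

test_that("multi-k embedding concatenates in ascending-k order", {
  m3 <- fake_model(rbind(ACG = c(1, 0), CGT = c(0, 1), GTA = c(1, 1),
                         TAC = c(0, 0)), 3L)
  all2 <- .codes_to_kmers_cpp(0:15, 2L)
  m2 <- fake_model(matrix(5, 16, 2, dimnames = list(all2, NULL)), 2L)
  v <- embed_multi_k("ACGTA", list(m3, m2))
  expect_length(v, 8L)
  expect_equal(v[1:4], rep(5, 4))  # k = 2 block first despite input order
  expect_equal(v, embed_multi_k("ACGTA", list(m2, m3)))
  v1 <- embed_multi_k("ACGTA", list(m3))
  expect_equal(v1, embed_sequence(tokenize_bikmer("ACGTA", 3), m3)$values)
  expect_error(embed_multi_k("ACGTA", list(m3, m3)), "distinct")
})

test_that("KFVs count forward windows in lexicographic order", {
  f <- kfv("AAAA", 2)
  expect_length(f$counts, 16L)
  expect_equal(f$counts[1], 3L)       # AA
  expect_equal(sum(f$counts), 3L)     # = floor((4-2)/1) + 1
  f1 <- kfv("ACGT", 1, normalize = TRUE)
  expect_equal(f1$counts, rep(0.25, 4))
  expect_length(kfv(strrep("ACGT", 3), 5)$counts, 4^5)
  expect_error(kfv("AC", 3), "shorter")
  # counts sum to the window count under any stride
  set.seed(2)
  for (i in 1:10) {
    len <- sample(8:40, 1); k <- sample(1:4, 1); st <- sample(1:3, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    expect_equal(sum(kfv(s, k, stride = st)$counts),
                 floor((len - k) / st) + 1)
  }
})

test_that("embeddings round-trip through word2vec text format", {
  corpus <- list(c("AC", "CG", "GT", "AC"), c("TT", "AC", "CG"))
  m <- train_embedding(corpus, N = 6, epochs = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".txt")
  write_embedding(m, f)
  lines <- readLines(f)
  expect_equal(lines[1], paste(nrow(m$vectors), 6))
  back <- read_embedding(f)
  expect_equal(back$k, 2L)
  expect_equal(back$vectors, m$vectors, tolerance = 1e-6)
})
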