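#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance of each read against a same-length reference.
// Reads whose length differs from the reference get -1 (caller must
// fall back to an alignment-based comparison for those).
// [[Rcpp::export]]
IntegerVector mismatch_counts_cpp(CharacterVector reads, std::string ref) {
  const int n = reads.size();
  const int L = (int) ref.size();
  const char *rf = ref.c_str();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(reads, i);
    if (s == NA_STRING || LENGTH(s) != L) { out[i] = -1; continue; }
    const char *r = CHAR(s);
    int mm = 0;
    for (int j = 0; j < L; ++j) if (r[j] != rf[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// Classify the codon at each designed position of each read projected
// onto reference coordinates: 0 = wild-type codon, 1 = designed mutant
// codon, 2 = anything else (sequencing error, '-' from a deletion, or
// a truncated read). starts1 holds the 1-based first base of each codon.
// [[Rcpp::export]]
IntegerMatrix codon_states_cpp(CharacterVector reads, IntegerVector starts1,
                               CharacterVector wt_codons,
                               CharacterVector mut_codons) {
  const int n = reads.size();
  const int m = starts1.size();
  IntegerMatrix out(n, m);
  std::vector<std::string> wt(m), mu(m);
  for (int k = 0; k < m; ++k) {
    wt[k] = as<std::string>(wt_codons[k]);
    mu[k] = as<std::string>(mut_codons[k]);
  }
  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(reads, i);
    if (s == NA_STRING) { for (int k = 0; k < m; ++k) out(i, k) = 2; continue; }
    const char *r = CHAR(s);
    const int len = LENGTH(s);
    for (int k = 0; k < m; ++k) {
      const int p = starts1[k] - 1;
      if (p < 0 || p + 3 > len) { out(i, k) = 2; continue; }
      const char *w = wt[k].c_str();
      const char *u = mu[k].c_str();
      if (r[p] == w[0] && r[p + 1] == w[1] && r[p + 2] == w[2]) out(i, k) = 0;
      else if (r[p] == u[0] && r[p + 1] == u[1] && r[p + 2] == u[2]) out(i, k) = 1;
      else out(i, k) = 2;
    }
  }
  return out;
}

// Draw reads from template sequences (idx1 is 1-based per read) and add
// substitution errors at rate `error_rate` per base. The error count per
// read is Binomial(L, rate) with positions drawn uniformly; at the read
// accuracies modelled here (<= 1%) position collisions are negligible.
// Uses R's RNG so output is reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector sample_reads_cpp(CharacterVector templates, IntegerVector idx1,
                                 double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = idx1.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(templates[idx1[i] - 1]);
    const int L = (int) s.size();
    if (error_rate > 0 && L > 0) {
      int ne = (int) R::rbinom((double) L, error_rate);
      for (int e = 0; e < ne; ++e) {
        int pos = (int) (unif_rand() * L);
        if (pos >= L) pos = L - 1;
        const char cur = s[pos];
        char nb = cur;
        for (int tries = 0; tries < 16 && nb == cur; ++tries)
          nb = bases[(int) (unif_rand() * 4) & 3];
        s[pos] = nb;
      }
    }
    out[i] = s;
  }
  return out;
}

// Comma-joined sorted-by-column mutation-id key per read from a 0/1/2
// states matrix (column order == design order, already positional).
// [[Rcpp::export]]
CharacterVector genotype_keys_cpp(IntegerMatrix st, CharacterVector ids) {
  const int n = st.nrow(), m = st.ncol();
  std::vector<std::string> id(m);
  for (int k = 0; k < m; ++k) id[k] = as<std::string>(ids[k]);
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int k = 0; k < m; ++k) {
      if (st(i, k) == 1) {
        if (!buf.empty()) buf += ',';
        buf += id[k];
      }
    }
    out[i] = buf;
  }
  return out;
}

// DNA alphabet scan: per read, 0 = clean uppercase ACGTN, 1 = contains
// lowercase acgtn (needs uppercasing), 2 = contains a non-DNA character.
// [[Rcpp::export]]
IntegerVector dna_flags_cpp(CharacterVector reads) {
  const int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(reads, i);
    if (s == NA_STRING) { out[i] = 2; continue; }
    const char *r = CHAR(s);
    const int L = LENGTH(s);
    int flag = 0;
    for (int j = 0; j < L; ++j) {
      const char c = r[j];
      if (c=='A'||c=='C'||c=='G'||c=='T'||c=='N') continue;
      if (c=='a'||c=='c'||c=='g'||c=='t'||c=='n') { if (flag < 1) flag = 1; continue; }
      flag = 2; break;
    }
    out[i] = flag;
  }
  return out;
}
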