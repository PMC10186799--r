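#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Ungapped seed-and-extend read mapper against a pangenome of gene cluster
// sequences, plus a per-base pileup accumulator. Genes are short (<= a few kb)
// and few (hundreds), so a flat hash of forward-strand k-mers is sufficient.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

// encode k-mer starting at s[off]; returns false on non-ACGT
static bool encode_kmer(const std::string& s, int off, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[off + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

struct Candidate {
  int gene;    // 0-based
  int start;   // 0-based on gene forward strand
  int orient;  // 0 = forward, 1 = reverse-complement
  bool operator<(const Candidate& o) const {
    if (gene != o.gene) return gene < o.gene;
    if (start != o.start) return start < o.start;
    return orient < o.orient;
  }
  bool operator==(const Candidate& o) const {
    return gene == o.gene && start == o.start && orient == o.orient;
  }
};

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector read_seqs, CharacterVector gene_seqs,
                   int k, double max_mismatch_frac) {
  int n_genes = gene_seqs.size();
  int n_reads = read_seqs.size();
  std::vector<std::string> genes(n_genes);
  for (int g = 0; g < n_genes; ++g) genes[g] = as<std::string>(gene_seqs[g]);

  // index forward-strand k-mers: kmer -> packed (gene << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  for (int g = 0; g < n_genes; ++g) {
    const std::string& s = genes[g];
    int glen = (int)s.size();
    for (int p = 0; p + k <= glen; ++p) {
      uint64_t key;
      if (encode_kmer(s, p, k, key))
        index[key].push_back(((uint64_t)g << 32) | (uint64_t)p);
    }
  }

  // status per read: 0 mapped, 1 unmapped, 2 ambiguous, 3 skipped (non-ACGT)
  IntegerVector status(n_reads);
  std::vector<int> out_read, out_gene, out_start, out_rc, out_nm;

  std::string rc;
  std::vector<Candidate> cands;
  for (int r = 0; r < n_reads; ++r) {
    std::string read = as<std::string>(read_seqs[r]);
    int L = (int)read.size();
    bool clean = true;
    for (int i = 0; i < L; ++i)
      if (base_code(read[i]) < 0) { clean = false; break; }
    if (!clean) { status[r] = 3; continue; }
    if (L < k) { status[r] = 1; continue; }

    rc.assign(L, 'N');
    for (int i = 0; i < L; ++i) rc[L - 1 - i] = comp_base(read[i]);

    cands.clear();
    for (int orient = 0; orient < 2; ++orient) {
      const std::string& q = orient == 0 ? read : rc;
      for (int off = 0; off + k <= L; off += k) {
        uint64_t key;
        if (!encode_kmer(q, off, k, key)) continue;
        std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
          index.find(key);
        if (it == index.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int g = (int)(it->second[h] >> 32);
          int p = (int)(it->second[h] & 0xffffffffULL);
          int gstart = p - off;
          if (gstart < 0 || gstart + L > (int)genes[g].size()) continue;
          Candidate c; c.gene = g; c.start = gstart; c.orient = orient;
          cands.push_back(c);
        }
      }
    }
    if (cands.empty()) { status[r] = 1; continue; }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best_nm = L + 1;
    std::vector<int> best_idx;
    for (size_t c = 0; c < cands.size(); ++c) {
      const std::string& q = cands[c].orient == 0 ? read : rc;
      const std::string& g = genes[cands[c].gene];
      int nm = 0;
      for (int i = 0; i < L && nm <= best_nm; ++i)
        if (q[i] != g[cands[c].start + i]) ++nm;
      if (nm < best_nm) { best_nm = nm; best_idx.clear(); best_idx.push_back((int)c); }
      else if (nm == best_nm) best_idx.push_back((int)c);
    }
    if ((double)best_nm > max_mismatch_frac * (double)L + 1e-12) {
      status[r] = 1; continue;
    }
    bool multi_gene = false;
    for (size_t i = 1; i < best_idx.size(); ++i)
      if (cands[best_idx[i]].gene != cands[best_idx[0]].gene) { multi_gene = true; break; }
    if (multi_gene) { status[r] = 2; continue; }

    // co-best on one gene: candidates are sorted, take the first (lowest
    // start, forward orientation preferred at equal start)
    const Candidate& b = cands[best_idx[0]];
    status[r] = 0;
    out_read.push_back(r + 1);
    out_gene.push_back(b.gene + 1);
    out_start.push_back(b.start);
    out_rc.push_back(b.orient);
    out_nm.push_back(best_nm);
  }

  return List::create(
    _["read_idx"] = wrap(out_read), _["gene_idx"] = wrap(out_gene),
    _["start"] = wrap(out_start), _["rc"] = wrap(out_rc),
    _["n_mismatch"] = wrap(out_nm), _["status"] = status);
}

// Pileup of ungapped alignments. gene_offsets gives each gene's first row in
// the concatenated position space; aligned_seqs are already on the gene's
// forward strand. Returns total_len x 4 count matrix (A,C,G,T columns).
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(IntegerVector gene_idx, IntegerVector starts,
                         CharacterVector aligned_seqs, IntegerVector gene_offsets,
                         int total_len) {
  IntegerMatrix counts(total_len, 4);
  int n = gene_idx.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(aligned_seqs[i]);
    int base0 = gene_offsets[gene_idx[i] - 1] + starts[i];
    for (int j = 0; j < (int)s.size(); ++j) {
      int c = base_code(s[j]);
      if (c >= 0) counts(base0 + j, c) += 1;
    }
  }
  return counts;
}
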