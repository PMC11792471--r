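#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

// Scoring scheme: substitution matrix indexed through a 256-entry char lookup.
struct Scoring {
  int lut[256];
  std::vector<int> mat;
  int n;
  int go, ge; // gap of length L costs go + L * ge

  inline int score(char a, char b) const {
    return mat[lut[(unsigned char)a] * n + lut[(unsigned char)b]];
  }
  inline bool valid(char a) const { return lut[(unsigned char)a] >= 0; }
};

static Scoring make_scoring(const IntegerMatrix& S, const std::string& alphabet,
                            int go, int ge) {
  Scoring sc;
  sc.n = (int)alphabet.size();
  sc.go = go;
  sc.ge = ge;
  for (int i = 0; i < 256; i++) sc.lut[i] = -1;
  for (int i = 0; i < sc.n; i++) sc.lut[(unsigned char)alphabet[i]] = i;
  sc.mat.resize((size_t)sc.n * sc.n);
  for (int i = 0; i < sc.n; i++)
    for (int j = 0; j < sc.n; j++) sc.mat[(size_t)i * sc.n + j] = S(i, j);
  return sc;
}

struct Aln {
  int score = 0;
  int matches = 0;
  int len = 0; // alignment length including gap columns
};

// Smith-Waterman local alignment with affine gaps and full traceback.
// Tie preference in the DP: alignment start (0) < diagonal < gap-in-subject <
// gap-in-query, taking the later option only on strict improvement.
static Aln sw_align(const std::string& a, const std::string& b, const Scoring& sc,
                    std::vector<uint8_t>& tb) {
  Aln res;
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return res;

  tb.assign((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fv(m + 1, NEG_INF);

  int best = 0, bi = 0, bj = 0;
  const int open_cost = sc.go + sc.ge;

  for (int i = 1; i <= n; i++) {
    int E = NEG_INF;
    Hcur[0] = 0;
    const char ai = a[i - 1];
    uint8_t* tbrow = &tb[(size_t)i * (m + 1)];
    for (int j = 1; j <= m; j++) {
      uint8_t t = 0;
      int openE = Hcur[j - 1] - open_cost;
      int extE = E - sc.ge;
      if (extE > openE) { E = extE; t |= 4; } else { E = openE; }
      int openF = Hprev[j] - open_cost;
      int extF = Fv[j] - sc.ge;
      if (extF > openF) { Fv[j] = extF; t |= 8; } else { Fv[j] = openF; }
      int h = 0;
      uint8_t dir = 0;
      int diag = Hprev[j - 1] + sc.score(ai, b[j - 1]);
      if (diag > h) { h = diag; dir = 1; }
      if (E > h) { h = E; dir = 2; }
      if (Fv[j] > h) { h = Fv[j]; dir = 3; }
      Hcur[j] = h;
      tbrow[j] = t | dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  res.score = best;
  if (best == 0) return res;

  // Traceback (state machine over H / gap-in-subject / gap-in-query states).
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      uint8_t dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        res.len++;
        if (a[i - 1] == b[j - 1]) res.matches++;
        i--; j--;
      } else if (dir == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      res.len++;
      bool ext = t & 4;
      j--;
      state = ext ? 1 : 0;
    } else {
      res.len++;
      bool ext = t & 8;
      i--;
      state = ext ? 2 : 0;
    }
  }
  return res;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string subject,
                  IntegerMatrix score_matrix, std::string alphabet,
                  int gap_open, int gap_extend) {
  Scoring sc = make_scoring(score_matrix, alphabet, gap_open, gap_extend);
  for (char c : query)
    if (!sc.valid(c)) stop("invalid residue '%s' in query", std::string(1, c));
  for (char c : subject)
    if (!sc.valid(c)) stop("invalid residue '%s' in subject", std::string(1, c));
  std::vector<uint8_t> tb;
  Aln r = sw_align(query, subject, sc, tb);
  return List::create(
      _["score"] = r.score, _["matching_residues"] = r.matches,
      _["alignment_length"] = r.len,
      _["identity"] = r.len > 0 ? (double)r.matches / r.len : NA_REAL);
}

static inline int ntcode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char ntcomp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

// Translated six-frame search of nucleotide reads against an amino-acid
// reference set. Candidate references are pre-screened with exact amino-acid
// k-mer seeds; candidates are then aligned with the Smith-Waterman core.
// The single best hit (highest score; ties broken by the lowest reference
// index, i.e. lexicographically smallest sequence_id when refs are sorted)
// meeting both the identity and alignment-length thresholds is reported.
// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector read_ids, CharacterVector reads,
                        CharacterVector ref_ids, CharacterVector ref_seqs,
                        CharacterVector codons, CharacterVector codon_aas,
                        IntegerMatrix score_matrix, std::string alphabet,
                        int gap_open, int gap_extend, double min_identity,
                        int min_alignment_len, int seed_kmer) {
  Scoring sc = make_scoring(score_matrix, alphabet, gap_open, gap_extend);

  // genetic code lookup: codon index (16*a+4*b+c) -> amino acid char
  char aa_of[64];
  std::fill(aa_of, aa_of + 64, 'X');
  for (int i = 0; i < codons.size(); i++) {
    std::string cdn = as<std::string>(codons[i]);
    std::string aa = as<std::string>(codon_aas[i]);
    if (cdn.size() != 3 || aa.size() != 1) stop("malformed genetic code entry");
    int c1 = ntcode(cdn[0]), c2 = ntcode(cdn[1]), c3 = ntcode(cdn[2]);
    if (c1 < 0 || c2 < 0 || c3 < 0) stop("malformed codon in genetic code");
    aa_of[16 * c1 + 4 * c2 + c3] = aa[0];
  }

  // amino-acid 5-bit codes for k-mer seeds; only the 20 standard residues seed
  int aa_code[256];
  std::fill(aa_code, aa_code + 256, -1);
  {
    const std::string std20 = "ACDEFGHIKLMNPQRSTVWY";
    for (size_t i = 0; i < std20.size(); i++)
      aa_code[(unsigned char)std20[i]] = (int)i;
  }
  const int k = seed_kmer;
  const uint64_t kmask = (k >= 13) ? ~0ULL : ((1ULL << (5 * k)) - 1);

  int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  std::unordered_map<uint64_t, std::vector<int>> index;
  // bit filter in front of the hash map: one cache-resident probe rejects
  // the vast majority of background k-mers
  const int FBITS = 22;
  std::vector<uint64_t> filter(1ULL << (FBITS - 6), 0);
  auto fhash = [](uint64_t key) {
    return (key * 0x9E3779B97F4A7C15ULL) >> (64 - FBITS);
  };
  for (int r = 0; r < nref; r++) {
    refs[r] = as<std::string>(ref_seqs[r]);
    const std::string& s = refs[r];
    uint64_t key = 0;
    int run = 0;
    for (size_t p = 0; p < s.size(); p++) {
      int c = aa_code[(unsigned char)s[p]];
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 5) | (uint64_t)c) & kmask;
      if (++run >= k) {
        std::vector<int>& v = index[key];
        if (v.empty() || v.back() != r) v.push_back(r);
        uint64_t h = fhash(key);
        filter[h >> 6] |= (1ULL << (h & 63));
      }
    }
  }

  std::vector<std::string> out_read, out_ref;
  std::vector<int> out_score, out_match, out_len;
  std::vector<double> out_ident;
  std::vector<uint8_t> tbbuf;
  std::vector<int> cand;
  std::string frames[6];

  for (int ri = 0; ri < reads.size(); ri++) {
    std::string nt = as<std::string>(reads[ri]);
    int L = (int)nt.size();
    if (L < 3 * min_alignment_len) continue;
    std::string rc(L, 'N');
    for (int p = 0; p < L; p++) rc[L - 1 - p] = ntcomp(nt[p]);

    for (int f = 0; f < 6; f++) {
      const std::string& src = (f < 3) ? nt : rc;
      int off = f % 3;
      std::string& pep = frames[f];
      pep.clear();
      for (int p = off; p + 2 < L; p += 3) {
        int c1 = ntcode(src[p]), c2 = ntcode(src[p + 1]), c3 = ntcode(src[p + 2]);
        pep.push_back((c1 < 0 || c2 < 0 || c3 < 0) ? 'X'
                                                   : aa_of[16 * c1 + 4 * c2 + c3]);
      }
    }

    int best_score = -1, best_ref = -1, best_match = 0, best_len = 0;
    for (int f = 0; f < 6; f++) {
      const std::string& pep = frames[f];
      if ((int)pep.size() < k) continue;
      cand.clear();
      uint64_t key = 0;
      int run = 0;
      for (size_t p = 0; p < pep.size(); p++) {
        int c = aa_code[(unsigned char)pep[p]];
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 5) | (uint64_t)c) & kmask;
        if (++run >= k) {
          uint64_t h = fhash(key);
          if (filter[h >> 6] & (1ULL << (h & 63))) {
            auto it = index.find(key);
            if (it != index.end())
              cand.insert(cand.end(), it->second.begin(), it->second.end());
          }
        }
      }
      if (cand.empty()) continue;
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (int r : cand) {
        Aln a = sw_align(pep, refs[r], sc, tbbuf);
        if (a.len < min_alignment_len) continue;
        if ((double)a.matches / (double)a.len < min_identity - 1e-12) continue;
        if (a.score > best_score ||
            (a.score == best_score && r < best_ref)) {
          best_score = a.score;
          best_ref = r;
          best_match = a.matches;
          best_len = a.len;
        }
      }
    }

    if (best_ref >= 0) {
      out_read.push_back(as<std::string>(read_ids[ri]));
      out_ref.push_back(as<std::string>(ref_ids[best_ref]));
      out_score.push_back(best_score);
      out_match.push_back(best_match);
      out_len.push_back(best_len);
      out_ident.push_back((double)best_match / (double)best_len);
    }
    if (ri % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(
      _["read_id"] = out_read, _["sequence_id"] = out_ref,
      _["score"] = out_score, _["matching_residues"] = out_match,
      _["alignment_length"] = out_len, _["identity"] = out_ident,
      _["stringsAsFactors"] = false);
}
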