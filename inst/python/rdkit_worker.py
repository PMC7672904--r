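"""RDKit chemistry worker.

Serves molecule/reaction primitives to the R package over a localhost
socket, one JSON object per line in, one per line out.  Started by the R
side with the path of a hand-shake file as the only argument; the worker
binds an ephemeral port, writes the port number to that file and accepts a
single connection.  It exits when the connection closes.
"""

import json
import socket
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

_MOL_CACHE = {}
_RXN_CACHE = {}


def _mol(smiles):
    if smiles not in _MOL_CACHE:
        _MOL_CACHE[smiles] = Chem.MolFromSmiles(smiles)
    return _MOL_CACHE[smiles]


def _rxn(smarts):
    if smarts not in _RXN_CACHE:
        try:
            rxn = AllChem.ReactionFromSmarts(smarts)
            if rxn is not None:
                rxn.Initialize()
        except Exception:
            rxn = None
        _RXN_CACHE[smarts] = rxn
    return _RXN_CACHE[smarts]


def op_parse(req):
    mol = _mol(req["smiles"])
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    smi = Chem.MolToSmiles(mol)
    try:
        key = Chem.MolToInchiKey(mol)
    except Exception:
        key = ""
    if not key:
        key = "SMI:" + smi
    n_carbons = sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() == 6)
    return {
        "ok": True,
        "smiles": smi,
        "key": key,
        "n_carbons": n_carbons,
        "n_atoms": mol.GetNumAtoms(),
    }


def op_parse_rxn(req):
    rxn = _rxn(req["smarts"])
    if rxn is None:
        return {"ok": False, "error": "unparsable reaction SMARTS"}
    return {
        "ok": True,
        "n_reactant_templates": rxn.GetNumReactantTemplates(),
        "n_product_templates": rxn.GetNumProductTemplates(),
    }


def _clean_fragments(out_mols):
    """Sanitize reaction outcome mols, split fragments, re-canonicalize.

    Returns (list of canonical SMILES, ok flag)."""
    frags = []
    for m in out_mols:
        try:
            Chem.SanitizeMol(m)
        except Exception:
            return None
        for f in Chem.GetMolFrags(m, asMols=True, sanitizeFrags=False):
            s = Chem.MolToSmiles(f)
            # round-trip: rejects radicals/valence errors surviving sanitize
            f2 = Chem.MolFromSmiles(s)
            if f2 is None:
                return None
            frags.append(Chem.MolToSmiles(f2))
    return frags


def op_apply(req):
    """Apply a (retro) single-reactant reaction SMARTS to one molecule."""
    rxn = _rxn(req["smarts"])
    if rxn is None:
        return {"ok": False, "error": "unparsable reaction SMARTS"}
    if rxn.GetNumReactantTemplates() != 1:
        return {"ok": False, "error": "expected exactly one reactant template"}
    mol = _mol(req["smiles"])
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    try:
        outcomes = rxn.RunReactants((mol,))
    except Exception:
        outcomes = ()
    sets, n_failed = [], 0
    for out in outcomes:
        frags = _clean_fragments(out)
        if frags is None:
            n_failed += 1
        else:
            sets.append(sorted(frags))
    return {"ok": True, "sets": sets, "n_failed": n_failed}


def op_apply_multi(req):
    """Apply a multi-reactant (forward) reaction SMARTS to a reactant tuple."""
    rxn = _rxn(req["smarts"])
    if rxn is None:
        return {"ok": False, "error": "unparsable reaction SMARTS"}
    mols = []
    for s in req["smiles_list"]:
        m = _mol(s)
        if m is None:
            return {"ok": False, "error": "unparsable SMILES: " + s}
        mols.append(m)
    if rxn.GetNumReactantTemplates() != len(mols):
        return {"ok": False, "error": "reactant count mismatch"}
    try:
        outcomes = rxn.RunReactants(tuple(mols))
    except Exception:
        outcomes = ()
    sets, n_failed = [], 0
    for out in outcomes:
        frags = _clean_fragments(out)
        if frags is None:
            n_failed += 1
        else:
            sets.append(sorted(frags))
    return {"ok": True, "sets": sets, "n_failed": n_failed}


def op_fingerprint(req):
    mol = _mol(req["smiles"])
    if mol is None:
        return {"ok": False, "error": "unparsable SMILES"}
    fp = AllChem.GetMorganFingerprintAsBitVect(
        mol, int(req["radius"]), nBits=int(req["nbits"])
    )
    # 1-based bit indices for the R side
    return {"ok": True, "bits": [b + 1 for b in fp.GetOnBits()]}


OPS = {
    "ping": lambda req: {"ok": True, "pong": True},
    "parse": op_parse,
    "parse_rxn": op_parse_rxn,
    "apply": op_apply,
    "apply_multi": op_apply_multi,
    "fingerprint": op_fingerprint,
}


def main():
    portfile = sys.argv[1]
    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.bind(("127.0.0.1", 0))
    srv.listen(1)
    srv.settimeout(300)
    with open(portfile, "w") as fh:
        fh.write("%d\n" % srv.getsockname()[1])
    try:
        conn, _ = srv.accept()
    except socket.timeout:
        return
    stream = conn.makefile("rwb")
    for line in stream:
        if not line.strip():
            continue
        try:
            req = json.loads(line)
            handler = OPS.get(req.get("op"))
            if handler is None:
                resp = {"ok": False, "error": "unknown op"}
            else:
                resp = handler(req)
        except Exception as exc:  # never die on a bad request
            resp = {"ok": False, "error": str(exc)}
        stream.write((json.dumps(resp) + "\n").encode())
        stream.flush()


if __name__ == "__main__":
    main()
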