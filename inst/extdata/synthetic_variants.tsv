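substitution	phenotype
A25L	lissencephaly
K35P	lissencephaly
G53L	lissencephaly
Y83E	lissencephaly
C20I	lissencephaly
E82S	lissencephaly
L87C	lissencephaly
D61I	lissencephaly
E58P	lissencephaly
W7C	lissencephaly
C20Q	lissencephaly
H17R	lissencephaly
G63L	lissencephaly
K55M	microlissencephaly
M46Q	microlissencephaly
F18G	microlissencephaly
E76M	microlissencephaly
M62Q	microlissencephaly
Q73G	microlissencephaly
F11V	microlissencephaly
E67L	microlissencephaly
Q39E	microlissencephaly
H75P	microlissencephaly
T60R	microlissencephaly
M72F	microlissencephaly
Y51W	microlissencephaly
L80E	pachygyria
P32L	pachygyria
Y77T	pachygyria
V33D	pachygyria
P32M	pachygyria
F44G	pachygyria
E82T	pachygyria
S79F	pachygyria
G37E	pachygyria
A71F	pachygyria
P88K	pachygyria
Y41S	pachygyria
V66A	pachygyria
L59I	polymicrogyria
R21G	polymicrogyria
E13V	polymicrogyria
R45N	polymicrogyria
I85L	polymicrogyria
K55A	polymicrogyria
I89K	polymicrogyria
E67S	polymicrogyria
V34I	polymicrogyria
E40T	polymicrogyria
P15K	polymicrogyria
A3G	polymicrogyria
V66G	polymicrogyria
F11A	polymicrogyria
S79M	not_available
G57K	not_available
Y52S	not_available
Q31H	not_available
I42H	not_available
W47Y	not_available
F18I	not_available
Q49S	not_available
Y8C	not_available
V26C	not_available
R21G	not_available
N27Q	not_available
E82M	not_available
I42P	not_available
M72Q	not_available
I81T	not_available
Q39S	not_available
W7R	not_available
P32A	not_available
E67N	not_available
P32H	not_available
E58Q	not_available
Y77T	not_available
S79C	not_available
G37I	not_available
Q36M	not_available
E82H	not_available
L59D	not_available
M68W	not_available
Q56I	not_available
Y83A	not_available
Q28L	not_available
C19P	not_available
I81L	not_available
W47Q	not_available
L80Y	not_available
C19T	not_available
S70R	not_available
E67H	not_available
A86P	not_available
Y51D	not_available
V66G	not_available
G37C	not_available
F11G	not_available
I85E	not_available
N27C	not_available
K55W	not_available
F11I	not_available
Y77D	not_available
I30H	not_available
M72H	not_available
V26P	not_available
R21E	not_available
F48Q	not_available
V26D	not_available
F18N	not_available
F48N	not_available
Y52M	not_available
E13I	not_available
A25G	not_available
V66F	not_available
P88C	not_available
F11E	not_available
S70I	not_available
L87G	not_available
H75A	not_available
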