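  a  c  d  e  f  g  h  i  k  l  m  n  p  q  r  s  t  v  w  y
a   6  -3   1  -3   1   1  -3  -3  -3  -3  -3   1   1  -3   1   1  -3  -3  -3  -3
c  -3   6  -3  -3  -3  -3   1  -3  -3   1  -3  -3  -3   1  -3  -3  -3   1  -3  -3
d   1  -3   6  -3   1   1  -3  -3  -3  -3  -3   1   1  -3   1   1  -3  -3  -3  -3
e  -3  -3  -3   6  -3  -3  -3   1   1  -3   1  -3  -3  -3  -3  -3   1  -3   1   1
f   1  -3   1  -3   6   1  -3  -3  -3  -3  -3   1   1  -3   1   1  -3  -3  -3  -3
g   1  -3   1  -3   1   6  -3  -3  -3  -3  -3   1   1  -3   1   1  -3  -3  -3  -3
h  -3   1  -3  -3  -3  -3   6  -3  -3   1  -3  -3  -3   1  -3  -3  -3   1  -3  -3
i  -3  -3  -3   1  -3  -3  -3   6   1  -3   1  -3  -3  -3  -3  -3   1  -3   1   1
k  -3  -3  -3   1  -3  -3  -3   1   6  -3   1  -3  -3  -3  -3  -3   1  -3   1   1
l  -3   1  -3  -3  -3  -3   1  -3  -3   6  -3  -3  -3   1  -3  -3  -3   1  -3  -3
m  -3  -3  -3   1  -3  -3  -3   1   1  -3   6  -3  -3  -3  -3  -3   1  -3   1   1
n   1  -3   1  -3   1   1  -3  -3  -3  -3  -3   6   1  -3   1   1  -3  -3  -3  -3
p   1  -3   1  -3   1   1  -3  -3  -3  -3  -3   1   6  -3   1   1  -3  -3  -3  -3
q  -3   1  -3  -3  -3  -3   1  -3  -3   1  -3  -3  -3   6  -3  -3  -3   1  -3  -3
r   1  -3   1  -3   1   1  -3  -3  -3  -3  -3   1   1  -3   6   1  -3  -3  -3  -3
s   1  -3   1  -3   1   1  -3  -3  -3  -3  -3   1   1  -3   1   6  -3  -3  -3  -3
t  -3  -3  -3   1  -3  -3  -3   1   1  -3   1  -3  -3  -3  -3  -3   6  -3   1   1
v  -3   1  -3  -3  -3  -3   1  -3  -3   1  -3  -3  -3   1  -3  -3  -3   6  -3  -3
w  -3  -3  -3   1  -3  -3  -3   1   1  -3   1  -3  -3  -3  -3  -3   1  -3   6   1
y  -3  -3  -3   1  -3  -3  -3   1   1  -3   1  -3  -3  -3  -3  -3   1  -3   1   6
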