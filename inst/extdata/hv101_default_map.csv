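raw_label,canonical
HEAD,head
WIFE OR HUSBAND,wife_or_husband
WIFE,wife_or_husband
HUSBAND,wife_or_husband
CO-SPOUSE,wife_or_husband
SON/DAUGHTER,son_or_daughter
SON OR DAUGHTER,son_or_daughter
SON,son_or_daughter
DAUGHTER,son_or_daughter
SON/DAUGHTER-IN-LAW,son_or_daughter_in_law
SON-IN-LAW OR DAUGHTER-IN-LAW,son_or_daughter_in_law
SON-IN-LAW,son_or_daughter_in_law
DAUGHTER-IN-LAW,son_or_daughter_in_law
PARENT,parent
FATHER,parent
MOTHER,parent
PARENT-IN-LAW,parent_in_law
FATHER-IN-LAW,parent_in_law
MOTHER-IN-LAW,parent_in_law
BROTHER/SISTER,sibling
BROTHER OR SISTER,sibling
BROTHER,sibling
SISTER,sibling
GRANDPARENT,grandparent
GRANDCHILD,grandchild
ADOPTED/FOSTER/STEPCHILD,adopted_child
ADOPTED/FOSTER CHILD,adopted_child
ADOPTED CHILD,adopted_child
FOSTER CHILD,adopted_child
STEPCHILD,adopted_child
OTHER RELATIVE,other_relative
NOT RELATED,not_related
DOMESTIC EMPLOYEE,not_related
OTHER,other
DK,other
DON'T KNOW,other
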